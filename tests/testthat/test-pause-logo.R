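test_that("pause-site calling keeps the top q% of region positions with
           deterministic tie-breaking", {
  # 1000 spacer positions + 500 mature
  tpl <- rdna_template("t", paste(rep("ACGT", 375), collapse = ""),
                       data.frame(name = c("ETS1", "18S"),
                                  start = c(1, 1001), end = c(1000, 1500),
                                  cls = c("spacer", "mature")))
  med <- rep(0, 1500)
  spikes <- seq(10, 970, by = 40)[1:25]
  med[spikes] <- 100 + seq_along(spikes)
  med[1200] <- 1e6  # mature positions must be ignored
  sites <- call_pause_sites(med, tpl, q = 2.5)
  expect_length(sites, 25)  # ceiling(2.5% of 1000)
  expect_equal(sites, sort(spikes))
  expect_length(call_pause_sites(med, tpl, q = 100), 1000)
  # ties broken toward the lower coordinate
  med2 <- rep(1, 1500)
  expect_equal(call_pause_sites(med2, tpl, q = 1), 1:10)
  expect_error(call_pause_sites(med, tpl, q = 0), "q must be")
})

test_that("context extraction matches direct substrings and drops
           boundary-violating positions", {
  tpl <- toy_template(seed = 51)
  ctx <- extract_contexts(tpl, c(1, 30, 60), window = 0)
  expect_equal(ctx$contexts,
               substring(tpl$sequence, c(1, 30, 60), c(1, 30, 60)))
  ctx2 <- extract_contexts(tpl, c(2, 50), window = -5:0)
  expect_equal(ctx2$dropped, 1)
  expect_equal(ctx2$contexts, substr(tpl$sequence, 45, 50))
  withr::with_seed(52, {
    pos <- sample(11:90, 30)
    ctx3 <- extract_contexts(tpl, pos, window = -10:5)
    expect_equal(ctx3$contexts, substring(tpl$sequence, pos - 10, pos + 5))
  })
  expect_error(extract_contexts(tpl, 50, window = 1:3), "offset 0")
})

test_that("PWM probabilities follow the pseudocount arithmetic", {
  pwm <- pwm_from_contexts(c("A", "A", "A"), pseudocount = 0)
  expect_equal(unname(pwm["A", 1]), 1)
  pwm2 <- pwm_from_contexts("A", pseudocount = 1)
  expect_equal(unname(pwm2[, 1]), c(2, 1, 1, 1) / 5)
  withr::with_seed(53, {
    for (i in 1:50) {
      ctx <- random_contexts(sample(1:20, 1), sample(1:6, 1))
      p <- pwm_from_contexts(ctx, pseudocount = 0.5)
      expect_equal(colSums(p), rep(1, ncol(p)), ignore_attr = TRUE)
      expect_true(all(p >= 0))
    }
  })
  expect_error(pwm_from_contexts(character()), "empty")
  expect_error(pwm_from_contexts(c("AA", "A")), "equal lengths")
})

test_that("JS divergence: identity, maximum, oracle agreement, bounds and
           symmetry", {
  expect_equal(js_divergence(c(.25, .25, .25, .25), c(.25, .25, .25, .25)), 0)
  expect_equal(js_divergence(c(1, 0, 0, 0), c(0, 1, 0, 0)), 1)
  p <- c(0.5, 0.5, 0, 0); q <- rep(0.25, 4)
  expect_equal(js_divergence(p, q), oracle_jsd(p, q))
  withr::with_seed(54, {
    for (i in 1:1000) {
      a <- as.vector(rmultinom(1, 40, runif(4))) / 40
      b <- as.vector(rmultinom(1, 40, runif(4))) / 40
      j <- js_divergence(a, b)
      expect_equal(j, oracle_jsd(a, b))
      expect_equal(j, js_divergence(b, a))
      expect_true(j >= 0 && j <= 1)
    }
  })
  expect_error(js_divergence(c(0.5, 0.5, 0.5, 0), rep(0.25, 4)),
               "probability")
})

test_that("diff_logo localizes divergence to differing offsets and its
           deltas sum to zero", {
  a <- pwm_from_contexts(c("AC", "AC", "AT"), pseudocount = 0.5)
  expect_equal(diff_logo(a, a)$table$jsd, c(0, 0))
  expect_equal(diff_logo(a, a)$letter_deltas,
               matrix(0, 4, 2, dimnames = dimnames(a)), ignore_attr = TRUE)
  b <- pwm_from_contexts(c("GC", "GC", "GT"), pseudocount = 0.5)
  dl <- diff_logo(a, b)
  expect_gt(dl$table$jsd[1], 0)
  expect_equal(dl$table$jsd[2], 0)
  expect_equal(colSums(dl$letter_deltas), c(0, 0), ignore_attr = TRUE)
  # composition oracle: offset-wise js_divergence of the two PWMs
  withr::with_seed(55, {
    ca <- random_contexts(30, 4); cb <- random_contexts(25, 4)
    pa <- pwm_from_contexts(ca); pb <- pwm_from_contexts(cb)
    dl2 <- diff_logo(pa, pb)
    for (j in 1:4) {
      expect_equal(dl2$table$jsd[j], js_divergence(pa[, j], pb[, j]))
    }
  })
  expect_error(diff_logo(a, pwm_from_contexts(c("ACG"))), "windows")
})

test_that("permutation test: identical sets give p = 1, separated sets give
           the minimum attainable p", {
  ctx <- random_contexts(40, 3)
  pt <- permutation_test(ctx, ctx, n_perm = 99, seed = 1)
  expect_equal(pt$jsd, rep(0, 3))
  expect_equal(pt$p_perm, rep(1, 3))
  a <- rep("AGG", 50); b <- rep("CGG", 50)
  pt2 <- permutation_test(a, b, n_perm = 999, seed = 2)
  expect_equal(pt2$p_perm[1], 1 / 1000)
  expect_true(all(pt2$p_perm > 0 & pt2$p_perm <= 1))
  expect_error(permutation_test(a, b, n_perm = 50, seed = 1), ">= 99")
  expect_error(permutation_test(character(), b, seed = 1), "non-empty")
})

test_that("sampled permutation p approximates the exhaustive-split
           proportion on a 4+4 toy", {
  a <- c("AA", "AA", "AA", "AA")
  b <- c("CA", "CA", "CA", "CA")
  # exhaustive oracle over all C(8,4) = 70 splits of the pooled contexts
  pool <- c(a, b)
  splits <- utils::combn(8, 4)
  obs_stat <- function(ia) {
    pa <- pwm_from_contexts(pool[ia], 0.5)
    pb <- pwm_from_contexts(pool[-ia], 0.5)
    js_divergence(pa[, 1], pb[, 1])
  }
  obs <- obs_stat(1:4)
  exh <- mean(apply(splits, 2, function(ia) obs_stat(ia) >= obs - 1e-12))
  pt <- permutation_test(a, b, n_perm = 999, seed = 3)
  # sampled exceedance proportion should match the exhaustive one within
  # binomial 3 sigma (plus the +1 correction)
  phat <- pt$p_perm[1] - 1 / 1000
  expect_lt(abs(phat - exh * 999 / 1000), 3 * sqrt(exh * (1 - exh) / 999) +
              1e-3)
})

test_that("permutation p-values are uniform for label-exchangeable
           contexts", {
  withr::with_seed(56, {
    ps <- replicate(150, {
      ctx <- random_contexts(120, 3)
      pt <- permutation_test(ctx[1:60], ctx[61:120], n_perm = 199,
                             seed = sample.int(1e6, 1))
      pt$p_perm[2]
    })
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
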