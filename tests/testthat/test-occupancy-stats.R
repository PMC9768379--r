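prof_of <- function(counts, id, strain = "s") {
  normalize_profile(occupancy_profile(as.integer(counts), id, strain))
}

test_that("median occupancy matches a sort-and-pick oracle", {
  p1 <- prof_of(c(1, 5, 10), "a")
  p2 <- prof_of(c(3, 5, 8), "b")
  p3 <- prof_of(c(100, 5, 0), "c")
  med <- median_occupancy(list(p1, p2, p3))
  m <- cbind(p1$normalized, p2$normalized, p3$normalized)
  oracle <- apply(m, 1, function(v) sort(v)[2])
  expect_equal(med, oracle)
  # single replicate is the identity
  expect_equal(median_occupancy(list(p1)), p1$normalized)
})

test_that("positionwise Welch test matches the closed form and classifies
           by direction", {
  # use counts mode so values are the raw replicates given
  mk <- function(v, id) {
    p <- occupancy_profile(as.integer(v), id)
    p$normalized <- as.numeric(v)  # identity normalization for the oracle
    p
  }
  a <- list(mk(c(10, 1), "a1"), mk(c(10, 2), "a2"), mk(c(10, 3), "a3"))
  b <- list(mk(c(10, 101), "b1"), mk(c(10, 102), "b2"), mk(c(10, 103), "b3"))
  tt <- positionwise_ttest(a, b)
  # identical values at position 1 -> p = 1, no_change
  expect_equal(tt$p_value[1], 1)
  expect_equal(tt$cls[1], "no_change")
  # closed-form Welch at position 2: t = (102-2)/sqrt(1/3 + 1/3)
  tstat <- 100 / sqrt(2 / 3)
  df <- (2 / 3)^2 / (2 * (1 / 3)^2 / 2)
  expect_equal(tt$p_value[2], 2 * pt(-tstat, df))
  expect_equal(tt$cls[2], "increased")
  # strain swap flips the class with identical p
  tt_sw <- positionwise_ttest(b, a)
  expect_equal(tt_sw$p_value, tt$p_value)
  expect_equal(tt_sw$cls[2], "decreased")
  expect_error(positionwise_ttest(a[1], b), ">= 2")
})

test_that("KS region test matches the ECDF oracle and its edge cases", {
  tpl <- toy_template(seed = 44, len = 100, split = 40)
  ca <- rep(0L, 100); cb <- rep(0L, 100)
  ca[1:40] <- 5L; cb[1:40] <- 5L
  pa <- prof_of(ca, "a"); pb <- prof_of(cb, "b")
  r <- region_ks_test(pa, pb, tpl, "ETS1")
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  # all mass at region start vs region end
  ca2 <- rep(0L, 100); cb2 <- rep(0L, 100)
  ca2[1] <- 50L; cb2[40] <- 50L
  r2 <- region_ks_test(prof_of(ca2, "a"), prof_of(cb2, "b"), tpl, "ETS1")
  expect_equal(r2$D, 1)
  expect_lt(r2$p, 1e-6)
  # random multinomial profiles vs brute-force ECDF scan
  withr::with_seed(45, {
    for (i in 1:200) {
      xa <- as.integer(rmultinom(1, 500, prob = runif(40)))
      xb <- as.integer(rmultinom(1, 500, prob = runif(40)))
      fa <- rep(0L, 100); fb <- rep(0L, 100)
      fa[1:40] <- xa; fb[1:40] <- xb
      r3 <- region_ks_test(prof_of(fa, "a"), prof_of(fb, "b"), tpl, "ETS1")
      expect_equal(r3$D, oracle_ks_D(xa, xb))
    }
  })
  expect_error(region_ks_test(prof_of(ca2, "a"), prof_of(ca2, "b"),
                              tpl, "18S"), "reads in the region")
})

test_that("moving average is exact against the double-loop oracle", {
  expect_equal(moving_average(rep(3, 10), 5), rep(3, 10))
  x <- c(4, 8, 15, 16, 23, 42)
  expect_equal(moving_average(x, 1), x)
  withr::with_seed(46, {
    for (i in 1:50) {
      v <- rnorm(sample(3:50, 1))
      w <- sample(c(1, 3, 5, 7), 1)
      expect_equal(moving_average(v, w), oracle_movavg(v, w))
    }
  })
  expect_error(moving_average(x, 4), "odd")
})

test_that("ecdf table is a monotone step function matching rank/n", {
  t1 <- ecdf_table(5)
  expect_equal(t1$cdf, 1)
  withr::with_seed(47, {
    v <- sample(1:20, 50, replace = TRUE)
    tab <- ecdf_table(v)
    expect_true(all(diff(tab$cdf) > 0))
    expect_equal(tab$cdf[nrow(tab)], 1)
    oracle <- vapply(tab$value, function(x) mean(v <= x), numeric(1))
    expect_equal(tab$cdf, oracle)
  })
  expect_error(ecdf_table(numeric()), "empty")
})

test_that("spearman matrix matches rank-then-Pearson and handles
           degenerate profiles", {
  p1 <- prof_of(c(1, 2, 3, 4, 10), "a")
  expect_equal(spearman_matrix(list(p1, p1))[1, 2], 1)
  p_rev <- prof_of(c(10, 4, 3, 2, 1), "b")
  expect_equal(spearman_matrix(list(p1, p_rev))[1, 2], -1)
  withr::with_seed(48, {
    x <- rpois(30, 8) + 1L
    y <- rpois(30, 8) + 1L
    rho <- spearman_matrix(list(prof_of(x, "x"), prof_of(y, "y")))[1, 2]
    expect_equal(rho, cor(rank(x), rank(y)))
  })
  pc <- prof_of(rep(2, 5), "const")
  rho <- spearman_matrix(list(p1, pc))
  expect_true(is.na(rho[1, 2]))
  expect_equal(diag(rho), c(a = 1, const = 1))
})

test_that("PCA variance fractions behave on structured toy data", {
  g1 <- prof_of(c(10, 0, 0, 5), "g1a")
  g2 <- prof_of(c(0, 10, 5, 0), "g2a")
  res <- pca_variance(list(g1, g1, g2, g2))
  expect_equal(res$variance_fractions[1], 1)
  withr::with_seed(49, {
    profs <- lapply(1:4, function(i) prof_of(rpois(6, 20) + 1L,
                                             paste0("l", i)))
    res2 <- pca_variance(profs)
    expect_equal(sum(res2$variance_fractions), 1)
    expect_true(all(diff(res2$variance_fractions) <= 1e-12))
    # oracle: eigenvalues of the covariance of the centered matrix
    X <- t(sapply(profs, function(p) p$normalized))
    ev <- eigen(stats::cov(X), symmetric = TRUE)$values
    ev <- ev[ev > 1e-9]
    expect_equal(res2$variance_fractions[seq_along(ev)], ev / sum(ev),
                 tolerance = 1e-8)
  })
  expect_error(pca_variance(list(g1)), ">= 2")
})

test_that("KS p-values are uniform across repeated same-model library
           pairs", {
  tpl <- make_default_template(seed = 101)
  m0 <- build_pause_model(tpl, c(A = 0.8, C = 1.25, G = 0.8, T = 1.25))
  kp <- vapply(1:80, function(i) {
    a <- as_profile(simulate_netseq_library(m0, 3e4, seed = 1000 + 2 * i,
                                            library_id = "a"))
    b <- as_profile(simulate_netseq_library(m0, 3e4, seed = 1001 + 2 * i,
                                            library_id = "b"))
    region_ks_test(a, b, tpl, "ETS1")$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(kp, "punif")$p.value), 0.01)
})
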