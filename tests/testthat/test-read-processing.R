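test_that("deduplication keeps the first of identical records and is
           idempotent", {
  reads <- data.frame(
    id = paste0("r", 1:5),
    record = c("AAAACCCCGGGG", "AAAACCCCGGGG", "AAAACCCCGGGT",
               "TTTTCCCCGGGG", "AAAACCCCGGGG"),
    stringsAsFactors = FALSE)
  dd <- deduplicate_umis(reads, umi_len = 4)
  expect_equal(dd$removed, 2)
  expect_equal(dd$reads$id, c("r1", "r3", "r4"))
  dd2 <- deduplicate_umis(dd$reads, umi_len = 4)
  expect_equal(dd2$removed, 0)
  expect_identical(dd2$reads, dd$reads)
  expect_error(deduplicate_umis(data.frame(id = "x", record = "AC"),
                                umi_len = 4), "UMI")
})

test_that("dedup survivor set equals the brute-force unique-key set", {
  withr::with_seed(10, {
    recs <- paste0(random_contexts(60, 6), sample(c("GGTT", "CCAA"), 60, TRUE))
    reads <- data.frame(id = paste0("r", 1:60), record = recs,
                        stringsAsFactors = FALSE)
    dd <- deduplicate_umis(reads, umi_len = 6)
    # pairwise-comparison oracle: keep i if no j < i has the same record
    keep <- vapply(seq_along(recs), function(i) {
      !any(vapply(seq_len(i - 1), function(j) recs[j] == recs[i],
                  logical(1)))
    }, logical(1))
    expect_identical(dd$reads$record, recs[keep])
  })
})

test_that("adaptor trimming removes the longest matching suffix and
           discards adaptor-free reads", {
  adaptor <- "ATCTCGTATGCC"
  reads <- data.frame(
    id = c("full", "partial", "none"),
    record = c(paste0("AAAA", "ACGT", adaptor),       # full adaptor
               paste0("AAAA", "ACGTACGT", "ATCTC"),   # 5-nt prefix
               paste0("AAAA", "ACGTACGTACGT")),       # no adaptor
    stringsAsFactors = FALSE)
  tr <- trim_adaptor(reads, adaptor, umi_len = 4, min_overlap = 5)
  expect_equal(tr$discarded, 1)
  expect_equal(tr$reads$insert, c("ACGT", "ACGTACGT"))
  expect_equal(tr$reads$umi, c("AAAA", "AAAA"))
})

test_that("trimming agrees with the exhaustive suffix/prefix oracle", {
  adaptor <- "ATCTCGTATGCCGT"
  withr::with_seed(11, {
    for (i in 1:300) {
      core <- paste(sample(c("A", "C", "G", "T"),
                           sample(5:30, 1), replace = TRUE), collapse = "")
      ov <- sample(0:nchar(adaptor), 1)
      rest <- paste0(core, substr(adaptor, 1, ov))
      reads <- data.frame(id = "x", record = paste0("GGGG", rest),
                          stringsAsFactors = FALSE)
      got <- trim_adaptor(reads, adaptor, umi_len = 4, min_overlap = 4)
      want <- oracle_trim(rest, adaptor, min_overlap = 4)
      if (is.na(want)) {
        expect_equal(got$discarded, 1)
      } else {
        expect_equal(got$reads$insert, want)
      }
    }
  })
})

test_that("3'-end mapper places exact reads at their end position", {
  tpl <- make_default_template(seed = 21)
  read <- substr(tpl$sequence, 101, 140)
  prof <- map_three_prime_ends(
    data.frame(id = "a", insert = read, stringsAsFactors = FALSE), tpl)
  expect_equal(which(prof$counts > 0), 140)
  expect_equal(prof$stats$mapped, 1)

  # read shorter than min_match is unmapped, not an error
  prof2 <- map_three_prime_ends(
    data.frame(id = "b", insert = "ACGTACGTAC", stringsAsFactors = FALSE),
    tpl, min_match = 18)
  expect_equal(prof2$stats$unmapped, 1)
  expect_error(map_three_prime_ends(
    data.frame(id = "b", insert = read), tpl, min_match = 6), ">= 12")
})

test_that("reads matching an internal duplication are ambiguous", {
  block <- strrep("ACGGT", 6)  # 30-nt duplicated block
  withr::with_seed(22, {
    fill1 <- paste(sample(c("A", "C", "T"), 40, TRUE), collapse = "")
    fill2 <- paste(sample(c("A", "C", "T"), 40, TRUE), collapse = "")
  })
  seqs <- paste0(fill1, block, fill2, block)
  tpl <- toy_template(seq = seqs, split = 40)
  expect_equal(length(oracle_occurrences(seqs, block)), 2)
  prof <- map_three_prime_ends(
    data.frame(id = "dup", insert = block, stringsAsFactors = FALSE),
    tpl, min_match = 30)
  expect_equal(prof$stats$ambiguous, 1)
  expect_equal(prof$stats$mapped, 0)
})

test_that("mapper agrees with a sliding-window occurrence oracle on random
           reads", {
  tpl <- toy_template(seed = 33, len = 300, split = 100)
  k <- 12
  withr::with_seed(34, {
    for (i in 1:1000) {
      if (i %% 2 == 0) {
        end <- sample(k:300, 1)
        rng <- k:min(40, end)
        len <- if (length(rng) == 1) rng else sample(rng, 1)
        insert <- substr(tpl$sequence, end - len + 1, end)
      } else {
        insert <- paste(sample(c("A", "C", "G", "T"), sample(k:40, 1), TRUE),
                        collapse = "")
      }
      prof <- map_three_prime_ends(
        data.frame(id = "r", insert = insert, stringsAsFactors = FALSE),
        tpl, min_match = k)
      term <- substr(insert, nchar(insert) - k + 1, nchar(insert))
      hits <- oracle_occurrences(tpl$sequence, term)
      s <- prof$stats
      if (length(hits) == 0) {
        expect_equal(s$unmapped, 1)
      } else if (length(hits) > 1) {
        expect_equal(s$ambiguous, 1)
      } else {
        end_pos <- hits + k - 1
        start <- end_pos - nchar(insert) + 1
        full <- start >= 1 &&
          substr(tpl$sequence, start, end_pos) == insert
        if (full) {
          expect_equal(which(prof$counts > 0), end_pos)
        } else {
          expect_equal(s$unmapped, 1)
        }
      }
    }
  })
})

test_that("normalization is CPM and scale-invariant", {
  prof <- occupancy_profile(c(1L, 1L, 2L), "lib")
  prof <- normalize_profile(prof)
  expect_equal(prof$normalized, c(250000, 250000, 500000))
  prof10 <- normalize_profile(occupancy_profile(c(10L, 10L, 20L), "lib"))
  expect_equal(prof10$normalized, prof$normalized)
  withr::with_seed(35, {
    counts <- rpois(500, 3)
    counts[1] <- counts[1] + 1  # ensure nonzero
    p <- normalize_profile(occupancy_profile(counts, "lib"))
    expect_equal(sum(p$normalized), 1e6)
  })
  expect_error(normalize_profile(occupancy_profile(c(0L, 0L), "lib")),
               "all-zero")
})

test_that("full pipeline recovers true 3' ends and keeps the accounting
           identity", {
  tpl <- make_default_template(seed = 101)
  m <- build_pause_model(tpl, c(A = 0.8, C = 1.25, G = 0.8, T = 1.25))
  sim <- simulate_netseq_library(m, depth = 30000, contamination_frac = 0.1,
                                 seed = 36)
  prof <- process_library(sim$reads, tpl, umi_len = 8,
                          adaptor = sim$adaptor)
  s <- prof$stats
  expect_equal(s$input_reads,
               s$dedup_removed + s$no_adaptor + s$unmapped + s$ambiguous +
                 s$mapped)
  # recovery on non-truncated unique-record reads
  dd <- deduplicate_umis(sim$reads, 8)
  tr <- trim_adaptor(dd$reads, sim$adaptor, 8, 5)
  asg <- attr(map_three_prime_ends(tr$reads, tpl), "assignments")
  truth <- sim$truth[match(asg$id, sim$truth$id), ]
  non_trunc <- truth$true_end >= sim$read_len
  ok <- asg$status[non_trunc] == "mapped" &
    asg$position[non_trunc] == truth$true_end[non_trunc]
  expect_gte(mean(ok), 0.999)
  # truncated reads with >= min_match remaining are mappable too
  trunc <- truth$true_end < sim$read_len & truth$true_end >= 18
  if (any(trunc)) {
    expect_gte(mean(asg$position[trunc] == truth$true_end[trunc],
                    na.rm = TRUE), 0.999)
  }
})
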