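# Shared fixtures and independent brute-force oracles used across tests.

toy_template <- function(seq = NULL, seed = 7, len = 100,
                         split = 40, name = "toy") {
  if (is.null(seq)) {
    seq <- paste(withr::with_seed(seed,
      sample(c("A", "C", "G", "T"), len, replace = TRUE)), collapse = "")
  }
  len <- nchar(seq)
  rdna_template(name, seq, data.frame(
    name = c("ETS1", "18S"), start = c(1L, split + 1L),
    end = c(split, len), cls = c("spacer", "mature")))
}

# Linear scan: which region contains a 1-based position.
oracle_region_scan <- function(template, pos) {
  for (i in seq_len(nrow(template$regions))) {
    r <- template$regions[i, ]
    if (pos >= r$start && pos <= r$end) return(r$name)
  }
  NA_character_
}

# Exhaustive suffix/prefix scan for adaptor trimming.
oracle_trim <- function(rest, adaptor, min_overlap) {
  n <- nchar(rest)
  for (L in seq.int(min(n, nchar(adaptor)), 1L, by = -1L)) {
    if (L < min_overlap) break
    if (substr(rest, n - L + 1L, n) == substr(adaptor, 1L, L)) {
      return(substr(rest, 1L, n - L))
    }
  }
  NA_character_
}

# Count exact occurrences of `pat` in `s` by sliding window.
oracle_occurrences <- function(s, pat) {
  k <- nchar(pat)
  n <- nchar(s)
  if (k > n) return(integer())
  which(vapply(seq_len(n - k + 1L),
               function(i) substr(s, i, i + k - 1L) == pat, logical(1)))
}

# Naive double-loop centered moving average with truncated edges.
oracle_movavg <- function(x, w) {
  h <- (w - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    mean(x[idx])
  }, numeric(1))
}

# JSD via the Kullback-Leibler form: 0.5*KL(P||M) + 0.5*KL(Q||M), log2.
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# Brute-force two-sample KS D over positional count vectors.
oracle_ks_D <- function(ca, cb) {
  Fa <- cumsum(ca) / sum(ca)
  Fb <- cumsum(cb) / sum(cb)
  max(abs(Fa - Fb))
}

# Gap intervals as the complement of the union of footprints, on a fine
# grid refined analytically: returns data.frame(start, length).
oracle_gaps <- function(pos, L, fp) {
  h <- fp / 2
  if (!length(pos)) return(data.frame(start = 0, length = L))
  occ <- cbind(pos - h, pos + h)
  edges <- sort(c(0, as.vector(t(occ)), L))
  out <- NULL
  cur <- 0
  for (i in seq_along(pos)) {
    s <- occ[i, 1]
    if (s > cur) out <- rbind(out, c(cur, s - cur))
    cur <- max(cur, occ[i, 2])
  }
  if (cur < L) out <- rbind(out, c(cur, L - cur))
  data.frame(start = pmax(0, out[, 1]), length = out[, 2])
}

# Explicit loop histogram of start fractions into n equal bins.
oracle_bins <- function(fracs, n_bins) {
  counts <- integer(n_bins)
  for (f in fracs) {
    b <- min(floor(f * n_bins), n_bins - 1) + 1
    counts[b] <- counts[b] + 1
  }
  counts
}

seq_chars_test <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

read_tsv_meta_test <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

random_contexts <- function(n, w) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
  }, character(1))
}
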