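# Replicate- and strain-level occupancy statistics.

# Stack profiles into a positions x libraries matrix of normalized values.
profile_matrix <- function(profiles, value = c("normalized", "counts")) {
  value <- match.arg(value)
  stopifnot(length(profiles) >= 1L)
  vals <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "occupancy_profile"))
    v <- p[[value]]
    if (is.null(v)) stop("profile is not normalized; run normalize_profile()")
    v
  })
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L) stop("profiles have mismatched lengths")
  m <- do.call(cbind, vals)
  colnames(m) <- vapply(profiles, function(p) p$library_id, character(1))
  m
}

#' Per-position median occupancy across replicates
#'
#' @param profiles list of normalized [occupancy_profile]s on the same
#'   template.
#' @param value which values to take the median of.
#' @return numeric vector, one median per template position.
#' @export
median_occupancy <- function(profiles, value = c("normalized", "counts")) {
  m <- profile_matrix(profiles, match.arg(value))
  apply(m, 1L, stats::median)
}

#' Position-wise Welch t test between two replicate sets
#'
#' For each template position, a two-sided Welch (unequal-variance) t test
#' compares the normalized occupancy of strain A replicates against strain B
#' replicates. Positions are classified `increased` (p < alpha and strain-B
#' median above strain A), `decreased` (p < alpha and below), otherwise
#' `no_change`. Positions where both strains have zero variance and equal
#' means get p = 1 (no evidence either way, and no NaN propagation). No
#' multiple-testing correction is applied by default, matching a
#' per-position p < 0.05 coloring; set `p_adjust = "BH"` for an FDR-adjusted
#' classification.
#'
#' @param reps_a,reps_b lists of normalized [occupancy_profile]s (>= 2
#'   replicates each).
#' @param alpha significance level for classification.
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return `data.frame` with columns `position`, `median_a`, `median_b`,
#'   `p_value`, `cls`.
#' @export
positionwise_ttest <- function(reps_a, reps_b, alpha = 0.05,
                               p_adjust = "none") {
  A <- profile_matrix(reps_a)
  B <- profile_matrix(reps_b)
  if (ncol(A) < 2L || ncol(B) < 2L) stop("need >= 2 replicates per strain")
  if (nrow(A) != nrow(B)) stop("profiles have mismatched lengths")
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate & ma == mb] <- 1
  p[degenerate & ma != mb] <- 0
  p_used <- if (p_adjust == "none") p else stats::p.adjust(p, p_adjust)
  med_a <- apply(A, 1L, stats::median)
  med_b <- apply(B, 1L, stats::median)
  cls <- rep("no_change", nrow(A))
  sig <- p_used < alpha & med_a != med_b
  cls[sig & med_b > med_a] <- "increased"
  cls[sig & med_b < med_a] <- "decreased"
  data.frame(position = seq_len(nrow(A)), median_a = med_a,
             median_b = med_b, p_value = p_used, cls = cls,
             stringsAsFactors = FALSE)
}

# Asymptotic two-sample KS p-value for statistic D at effective size n_eff.
ks_asymptotic_p <- function(D, n_eff) {
  if (D <= 0) return(1)
  lam <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2))
  min(1, max(0, p))
}

#' Kolmogorov-Smirnov comparison of positional occupancy in a region
#'
#' Each strain's occupancy within the region is rescaled to a probability
#' distribution over positions; D is the maximum absolute difference of the
#' two positional ECDFs. The p-value uses the asymptotic two-sample KS
#' formula with effective sample sizes equal to the mapped read counts in
#' the region, capped at `cap` per strain so that read-level sample sizes in
#' the millions do not force p to 0 for trivial pattern differences.
#'
#' @param profile_a,profile_b normalized [occupancy_profile]s.
#' @param template the [rdna_template].
#' @param region region name (e.g. `"ETS1"`).
#' @param cap effective-sample-size cap per strain.
#' @return list with elements `region`, `D`, `p`, `n_eff`.
#' @export
region_ks_test <- function(profile_a, profile_b, template, region,
                           cap = 10000L) {
  pos <- region_positions(template, region)
  ca <- profile_a$counts[pos]
  cb <- profile_b$counts[pos]
  if (sum(ca) == 0L || sum(cb) == 0L) {
    stop("both profiles must have reads in the region")
  }
  Fa <- cumsum(ca / sum(ca))
  Fb <- cumsum(cb / sum(cb))
  D <- max(abs(Fa - Fb))
  n_a <- min(sum(ca), cap)
  n_b <- min(sum(cb), cap)
  n_eff <- n_a * n_b / (n_a + n_b)
  list(region = region, D = D, p = ks_asymptotic_p(D, n_eff), n_eff = n_eff)
}

#' Centered moving average with truncated edges
#'
#' @param values numeric vector.
#' @param window odd window width (>= 1); edge positions average over the
#'   part of the window inside the vector.
#' @return smoothed numeric vector of the same length.
#' @export
moving_average <- function(values, window) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  n <- length(values)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  lo <- pmax(0L, i - 1L - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Empirical CDF as a step-function table
#'
#' @param values non-empty numeric vector.
#' @return `data.frame` with columns `value` (sorted unique values) and
#'   `cdf` (right-continuous, terminal value 1).
#' @export
ecdf_table <- function(values) {
  if (!length(values)) stop("empty input")
  f <- stats::ecdf(values)
  v <- sort(unique(values))
  data.frame(value = v, cdf = f(v))
}

#' Pairwise Spearman correlation matrix of occupancy profiles
#'
#' Spearman rank correlation (average ranks for ties) of normalized
#' per-position values for every pair of libraries. A constant profile has
#' undefined rank correlation and yields `NA` against every other library.
#'
#' @param profiles list of >= 2 normalized [occupancy_profile]s.
#' @return symmetric correlation matrix with unit diagonal, dimnames =
#'   library ids.
#' @export
spearman_matrix <- function(profiles) {
  if (length(profiles) < 2L) stop("need >= 2 profiles")
  m <- profile_matrix(profiles)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' PCA of library occupancy profiles
#'
#' Principal component analysis of the libraries x positions matrix of
#' normalized counts, column-centered (covariance PCA, no scaling).
#'
#' @param profiles list of >= 2 normalized [occupancy_profile]s.
#' @return list with `variance_fractions` (non-increasing, summing to 1)
#'   and `scores` (libraries x components).
#' @export
pca_variance <- function(profiles) {
  if (length(profiles) < 2L) stop("need >= 2 profiles")
  X <- t(profile_matrix(profiles))  # libraries x positions
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) == 0) stop("profiles are identical; variance is zero")
  list(variance_fractions = v / sum(v), scores = pc$x)
}
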