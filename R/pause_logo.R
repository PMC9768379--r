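# Pause-site calling and differential sequence logos.

#' Call top-percentile pause sites
#'
#' Restricts to positions inside the named regions (by default all spacer
#' regions, which are free of mature-rRNA contamination) and returns the
#' `ceiling(q/100 * n)` positions of highest median normalized occupancy,
#' ties broken toward the lower coordinate.
#'
#' @param median_profile numeric vector of per-position median normalized
#'   occupancy (see [median_occupancy()]).
#' @param template the [rdna_template].
#' @param q percentile in `(0, 100]`; the experimental convention is the
#'   top 2.5% occupied positions.
#' @param regions region names or class passed to [region_positions()].
#' @return sorted integer vector of 1-based pause-site positions.
#' @export
call_pause_sites <- function(median_profile, template, q = 2.5,
                             regions = "spacer") {
  if (!(q > 0 && q <= 100)) stop("q must be in (0, 100]")
  pos <- region_positions(template, regions)
  if (length(median_profile) != template$length) {
    stop("median_profile length must equal template length")
  }
  n_top <- ceiling(q / 100 * length(pos))
  vals <- median_profile[pos]
  ord <- order(-vals, pos)
  sort(pos[ord[seq_len(n_top)]])
}

#' Extract sequence contexts around positions
#'
#' For each position `p`, the template letters at `p + offset` over the
#' window. Positions whose window would exit the template are dropped and
#' counted.
#'
#' @param template the [rdna_template].
#' @param positions 1-based positions (e.g. pause sites).
#' @param window integer offsets including 0 (0 = the position itself, the
#'   last incorporated nucleotide).
#' @return list with `contexts` (character vector), `window`, and
#'   `dropped` (count of out-of-range positions).
#' @export
extract_contexts <- function(template, positions, window = -10:5) {
  stopifnot(inherits(template, "rdna_template"))
  window <- sort(as.integer(window))
  if (!0L %in% window) stop("window must include offset 0")
  positions <- as.integer(positions)
  ok <- positions + min(window) >= 1L &
    positions + max(window) <= template$length
  kept <- positions[ok]
  chars <- seq_chars(template$sequence)
  ctx <- if (length(kept)) {
    m <- vapply(window, function(o) chars[kept + o], character(length(kept)))
    if (length(kept) == 1L) m <- matrix(m, nrow = 1L)
    apply(m, 1L, paste, collapse = "")
  } else {
    character()
  }
  list(contexts = ctx, window = window, dropped = sum(!ok))
}

#' Position weight matrix from aligned contexts
#'
#' Per-offset base probabilities `(count + pseudocount) / (n + 4 *
#' pseudocount)`. The default pseudocount 0.5 keeps entropies finite on
#' small context sets.
#'
#' @param contexts non-empty character vector of equal-length sequences.
#' @param pseudocount added to each base count.
#' @param window optional offsets used as column names.
#' @return object of class `pwm`: a 4 x width probability matrix (rows
#'   A,C,G,T), with attributes `n_contexts` and `window`.
#' @export
pwm_from_contexts <- function(contexts, pseudocount = 0.5, window = NULL) {
  if (!length(contexts)) stop("empty context list")
  wlen <- unique(nchar(contexts))
  if (length(wlen) != 1L) stop("contexts must have equal lengths")
  M <- matrix(match(unlist(strsplit(contexts, "", fixed = TRUE)), BASES),
              nrow = length(contexts), byrow = TRUE)
  if (any(is.na(M))) stop("contexts contain non-ACGT characters")
  n <- length(contexts)
  probs <- vapply(seq_len(wlen), function(j) {
    (tabulate(M[, j], 4L) + pseudocount) / (n + 4 * pseudocount)
  }, numeric(4))
  probs <- matrix(probs, nrow = 4L,
                  dimnames = list(BASES,
                                  if (is.null(window)) seq_len(wlen) - 1L
                                  else window))
  structure(probs, class = c("pwm", "matrix"), n_contexts = n,
            window = if (is.null(window)) NULL else sort(as.integer(window)))
}

# Shannon entropy in bits of a probability vector.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence between two base distributions
#'
#' `JSD(P, Q) = H(M) - (H(P) + H(Q)) / 2` with `M = (P + Q) / 2` and
#' entropies in bits; symmetric, bounded by `[0, 1]` bit for any pair of
#' distributions (the maximum is attained at disjoint supports).
#'
#' @param p,q probability vectors of equal length summing to 1 (tolerance
#'   1e-6).
#' @return divergence in bits.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("p and q must be probability distributions")
  }
  m <- (p + q) / 2
  max(0, entropy_bits(m) - (entropy_bits(p) + entropy_bits(q)) / 2)
}

# Per-offset JSD between two PWM-like probability matrices.
jsd_by_offset <- function(pa, pb) {
  vapply(seq_len(ncol(pa)),
         function(j) js_divergence(pa[, j], pb[, j]), numeric(1))
}

#' Differential sequence logo between two PWMs
#'
#' Per offset, the Jensen-Shannon divergence between the two base
#' distributions, and signed letter contributions `probs_b - probs_a`
#' (positive = enriched in strain B). When strain B is the mutant, its
#' enriched mass is conventionally rendered below the axis (negative JS
#' axis); numerically the divergence itself is kept non-negative and the
#' sign lives in the letter deltas.
#'
#' @param pwm_a,pwm_b [pwm_from_contexts()] results on identical windows.
#' @return object of class `difflogo`: list with `table` (`data.frame` of
#'   `offset`, `jsd`) and `letter_deltas` (4 x width matrix summing to 0
#'   per offset).
#' @export
diff_logo <- function(pwm_a, pwm_b) {
  if (ncol(pwm_a) != ncol(pwm_b) ||
      !identical(colnames(pwm_a), colnames(pwm_b))) {
    stop("PWM windows do not match")
  }
  offs <- suppressWarnings(as.integer(colnames(pwm_a)))
  if (any(is.na(offs))) offs <- seq_len(ncol(pwm_a)) - 1L
  structure(list(
    table = data.frame(offset = offs, jsd = jsd_by_offset(pwm_a, pwm_b)),
    letter_deltas = unclass(pwm_b) - unclass(pwm_a)),
    class = "difflogo")
}

#' Permutation test for per-offset composition differences
#'
#' Pools the two context sets, permutes set membership (sizes preserved),
#' and recomputes the per-offset Jensen-Shannon divergence between the
#' permuted-group PWMs. The p-value at each offset is
#' `(1 + #{permuted jsd >= observed}) / (n_perm + 1)`.
#'
#' @param contexts_a,contexts_b non-empty character vectors of equal-length
#'   contexts.
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed.
#' @param alpha significance level for the `significant` flag.
#' @param pseudocount passed to the internal PWM construction.
#' @return `data.frame` with columns `offset` (0-based column index unless
#'   the contexts carry window names), `jsd`, `p_perm`, `significant`.
#' @export
permutation_test <- function(contexts_a, contexts_b, n_perm = 999L,
                             seed = 1L, alpha = 0.05, pseudocount = 0.5) {
  if (!length(contexts_a) || !length(contexts_b)) {
    stop("both context sets must be non-empty")
  }
  if (n_perm < 99L) stop("n_perm must be >= 99")
  all_ctx <- c(contexts_a, contexts_b)
  wlen <- unique(nchar(all_ctx))
  if (length(wlen) != 1L) stop("contexts must have equal lengths")
  na <- length(contexts_a)
  n <- length(all_ctx)
  M <- matrix(match(unlist(strsplit(all_ctx, "", fixed = TRUE)), BASES),
              nrow = n, byrow = TRUE)
  if (any(is.na(M))) stop("contexts contain non-ACGT characters")
  tot <- vapply(seq_len(wlen), function(j) tabulate(M[, j], 4L), numeric(4))
  pwm_of <- function(cnt, sz) (cnt + pseudocount) / (sz + 4 * pseudocount)
  jsd_of_split <- function(ia) {
    ca <- vapply(seq_len(wlen), function(j) tabulate(M[ia, j], 4L),
                 numeric(4))
    cb <- tot - ca
    jsd_by_offset(pwm_of(ca, na), pwm_of(cb, n - na))
  }
  obs <- jsd_of_split(seq_len(na))
  exceed <- numeric(wlen)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- jsd_of_split(sample.int(n, na))
      exceed <- exceed + (perm >= obs)
    }
  })
  p <- (1 + exceed) / (n_perm + 1)
  data.frame(offset = seq_len(wlen) - 1L, jsd = obs, p_perm = p,
             significant = p < alpha)
}

#' Full differential-logo analysis between two strains
#'
#' Calls top-`q`% pause sites on each strain's replicate-median profile
#' (one logo per strain), extracts contexts over `window`, builds PWMs,
#' computes the differential logo and per-offset permutation p-values.
#'
#' @param median_a,median_b per-position median normalized occupancy for
#'   strains A (reference, e.g. WT) and B (e.g. mutant).
#' @param template the [rdna_template].
#' @param q top-percentile for pause-site calling.
#' @param window context-window offsets (0 = last incorporated nucleotide;
#'   default -10..+5 covers the RNA:DNA hybrid and downstream DNA).
#' @param regions regions searched for pause sites (default all spacers).
#' @param n_perm,seed,alpha,pseudocount see [permutation_test()].
#' @return object of class `pause_logo_result`: list with `sites_a`,
#'   `sites_b`, `pwm_a`, `pwm_b`, `letter_deltas` (B minus A), and `table`
#'   (`data.frame` of `offset`, `jsd`, `p_perm`, `significant`).
#' @export
pause_logo_compare <- function(median_a, median_b, template, q = 2.5,
                               window = -10:5, regions = "spacer",
                               n_perm = 999L, seed = 1L, alpha = 0.05,
                               pseudocount = 0.5) {
  sites_a <- call_pause_sites(median_a, template, q, regions)
  sites_b <- call_pause_sites(median_b, template, q, regions)
  ctx_a <- extract_contexts(template, sites_a, window)
  ctx_b <- extract_contexts(template, sites_b, window)
  pwm_a <- pwm_from_contexts(ctx_a$contexts, pseudocount, window = window)
  pwm_b <- pwm_from_contexts(ctx_b$contexts, pseudocount, window = window)
  dl <- diff_logo(pwm_a, pwm_b)
  pt <- permutation_test(ctx_a$contexts, ctx_b$contexts, n_perm, seed,
                         alpha, pseudocount)
  tab <- data.frame(offset = sort(window), jsd = dl$table$jsd,
                    p_perm = pt$p_perm, significant = pt$significant)
  structure(list(sites_a = sites_a, sites_b = sites_b,
                 pwm_a = pwm_a, pwm_b = pwm_b,
                 letter_deltas = dl$letter_deltas, table = tab),
            class = "pause_logo_result")
}

#' @export
print.pause_logo_result <- function(x, ...) {
  cat(sprintf(
    "<pause_logo_result> %d vs %d pause sites; %d/%d offsets significant\n",
    length(x$sites_a), length(x$sites_b),
    sum(x$table$significant), nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
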