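#' Sequence-context pause (dwell) model
#'
#' A `pause_model` assigns every template position a positive dwell weight:
#' the relative time a polymerase spends with its active site (last
#' incorporated nucleotide) at that position. NET-Seq occupancy is read as a
#' steady-state snapshot, so expected 3'-end density is proportional to
#' dwell. The dwell at position `i` is the product, over a context window of
#' offsets relative to the 3' end (offset 0 = last incorporated nucleotide;
#' negative offsets reach back into the RNA:DNA hybrid), of a per-base
#' weight applied to the nontemplate-strand base at `i + offset`, optionally
#' multiplied by a position-dependent bias, then rescaled to mean 1.
#'
#' @param template an [rdna_template].
#' @param context_weights named positive numeric vector `c(A=,C=,G=,T=)`;
#'   the weight applied for each base seen anywhere in the window.
#' @param window integer offsets relative to the 3' end; the default
#'   `-9:0` spans a 10-nt RNA:DNA-hybrid-sized context ending at the last
#'   incorporated nucleotide.
#' @param position_bias optional positive numeric vector of length
#'   `template$length`, multiplied into the dwell before rescaling (used to
#'   model position-dependent effects such as 5'-end pileups or runoff
#'   depletion downstream of persistent pauses).
#' @param strain label stored on the model.
#' @return object of class `pause_model` with elements `template`, `dwell`
#'   (mean 1), `context_weights`, `window`, `strain`.
#' @examples
#' tpl <- make_default_template(seed = 1)
#' m <- build_pause_model(tpl, c(A = 2, C = 1, G = 2, T = 1), window = -9:0)
#' mean(m$dwell)  # 1
#' @export
build_pause_model <- function(template,
                              context_weights = c(A = 1, C = 1, G = 1, T = 1),
                              window = -9:0,
                              position_bias = NULL,
                              strain = "strain") {
  stopifnot(inherits(template, "rdna_template"))
  if (!all(BASES %in% names(context_weights))) {
    stop("context_weights must be named with A, C, G, T")
  }
  w <- as.numeric(context_weights[BASES])
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("context weights must be positive")
  }
  window <- sort(as.integer(window))
  L <- template$length
  base_idx <- match(seq_chars(template$sequence), BASES)
  logw <- log(w)
  logd <- numeric(L)
  pos <- seq_len(L)
  for (o in window) {
    j <- pos + o
    ok <- j >= 1L & j <= L
    logd[ok] <- logd[ok] + logw[base_idx[j[ok]]]
  }
  dwell <- exp(logd)
  if (!is.null(position_bias)) {
    stopifnot(length(position_bias) == L, all(position_bias > 0))
    dwell <- dwell * position_bias
  }
  dwell <- dwell / mean(dwell)
  structure(list(template = template, dwell = dwell,
                 context_weights = stats::setNames(w, BASES),
                 window = window, strain = strain),
            class = "pause_model")
}

#' @export
print.pause_model <- function(x, ...) {
  cat(sprintf(
    "<pause_model> strain=%s on %s (%d nt); window %d..%d; weights %s\n",
    x$strain, x$template$name, x$template$length,
    min(x$window), max(x$window),
    paste(sprintf("%s=%.2g", names(x$context_weights), x$context_weights),
          collapse = " ")))
  cat(sprintf("  dwell: mean 1, range [%.3g, %.3g]\n",
              min(x$dwell), max(x$dwell)))
  invisible(x)
}

#' WT / mutant strain-pair scenario for NET-Seq emulation
#'
#' Returns the documented strong-effect default scenario used throughout the
#' package's synthetic analyses: a WT-like polymerase whose dwell favors
#' C/T-rich contexts and a trigger-loop-mutant-like polymerase sensitized to
#' A/G residues over the RNA:DNA-hybrid window (offsets -9..0), plus a
#' mutant 5'-end occupancy bias, `1 + 2 * exp(-(pos - 1) / 1000)`, emulating
#' the promoter-proximal pileup of a slowed, pause-prone enzyme. The strain
#' effect is deliberately strong: it redistributes a large fraction of
#' occupancy mass so that strain identity, not replicate sampling noise,
#' dominates library-level comparisons.
#'
#' @param template an [rdna_template].
#' @param seed integer; kept for API symmetry with the stochastic
#'   generators (the scenario itself is deterministic in the template).
#' @param wt_weights,mutant_weights named per-base context weights.
#' @param window context window (offsets relative to the 3' end).
#' @param mutant_tss_bias amplitude of the mutant 5' bias (multiplier at
#'   +1 is `1 + mutant_tss_bias`).
#' @param bias_scale decay length of the 5' bias, nt.
#' @return list of class `strain_scenario` with `pause_model`s `$wt` and
#'   `$mutant` and the parameter list `$params`.
#' @export
make_strain_pair_scenario <- function(template, seed = 1L,
                                      wt_weights = c(A = 0.7, C = 1.4,
                                                     G = 0.7, T = 1.4),
                                      mutant_weights = c(A = 1.4, C = 0.7,
                                                         G = 1.4, T = 0.7),
                                      window = -9:0,
                                      mutant_tss_bias = 2,
                                      bias_scale = 1000) {
  stopifnot(inherits(template, "rdna_template"))
  pos <- seq_len(template$length)
  bias <- 1 + mutant_tss_bias * exp(-(pos - 1) / bias_scale)
  wt <- build_pause_model(template, wt_weights, window, strain = "WT")
  mutant <- build_pause_model(template, mutant_weights, window,
                              position_bias = bias, strain = "mutant")
  structure(list(wt = wt, mutant = mutant,
                 params = list(seed = as.integer(seed),
                               wt_weights = wt_weights,
                               mutant_weights = mutant_weights,
                               window = window,
                               mutant_tss_bias = mutant_tss_bias,
                               bias_scale = bias_scale)),
            class = "strain_scenario")
}

#' WT / mutant pause models for Miller-spread emulation
#'
#' Miller chromatin spreads show occasional polymerase-free stretches
#' covering a quarter of the gene. In a snapshot model these require
#' gene-scale structure in the dwell profile, which short-range sequence
#' context cannot produce: summed over ~1,700 positions, context-driven
#' dwell fluctuations average out. This scenario therefore superimposes, on
#' the strain context weights, a persistent pause cluster (elevated dwell
#' just upstream of `runoff_window`) with runoff depletion downstream of it
#' (dwell multiplied by a small factor across the window), the static
#' signature of a pause-then-runoff event. The mutant's depletion is deeper
#' than WT's, so large gaps occur more often in the mutant, in the direction
#' of the experimental observation.
#'
#' @param template an [rdna_template].
#' @param runoff_window integer length-2 vector, 1-based closed bounds of
#'   the depleted window (default the 3'-proximal 2,000 nt starting at
#'   ~66% of the default 6,700-nt gene).
#' @param wt_depletion,mutant_depletion dwell multiplier inside the window.
#' @param cluster_boost dwell multiplier over the 50-nt pause cluster
#'   immediately upstream of the window.
#' @inheritParams make_strain_pair_scenario
#' @return list of class `strain_scenario` (same shape as
#'   [make_strain_pair_scenario()]).
#' @export
make_spread_scenario <- function(template,
                                 runoff_window = c(4400L, 6399L),
                                 wt_depletion = 0.13,
                                 mutant_depletion = 0.05,
                                 cluster_boost = 20,
                                 wt_weights = c(A = 0.9, C = 1.1,
                                                G = 0.9, T = 1.1),
                                 mutant_weights = c(A = 1.1, C = 0.9,
                                                    G = 1.1, T = 0.9),
                                 window = -9:0) {
  stopifnot(inherits(template, "rdna_template"))
  L <- template$length
  runoff_window <- pmin(pmax(as.integer(runoff_window), 1L), L)
  stopifnot(length(runoff_window) == 2L,
            runoff_window[1] < runoff_window[2],
            wt_depletion > 0, mutant_depletion > 0, cluster_boost > 0)
  make_bias <- function(depletion) {
    bias <- rep(1, L)
    bias[runoff_window[1]:runoff_window[2]] <- depletion
    cl <- max(1L, runoff_window[1] - 50L):(runoff_window[1] - 1L)
    if (runoff_window[1] > 1L) bias[cl] <- cluster_boost
    bias
  }
  wt <- build_pause_model(template, wt_weights, window,
                          position_bias = make_bias(wt_depletion),
                          strain = "WT")
  mutant <- build_pause_model(template, mutant_weights, window,
                              position_bias = make_bias(mutant_depletion),
                              strain = "mutant")
  structure(list(wt = wt, mutant = mutant,
                 params = list(runoff_window = runoff_window,
                               wt_depletion = wt_depletion,
                               mutant_depletion = mutant_depletion,
                               cluster_boost = cluster_boost)),
            class = "strain_scenario")
}
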