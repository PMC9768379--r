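#' Simulate Miller chromatin spread snapshots
#'
#' Each gene receives `rpois(1, target_density)` polymerases - actively
#' transcribed rDNA repeats carry on the order of 50 elongation complexes -
#' placed by dwell-weighted sequential sampling with hard-core exclusion: a
#' candidate active-site position is drawn in proportion to the pause
#' model's dwell and rejected if it falls within `footprint` of an already
#' accepted polymerase (or within half a footprint of a gene end), and
#' redrawn until the gene's polymerase count is placed.
#'
#' @param model a [pause_model]; the gene length is the template length.
#' @param n_genes number of genes (independent snapshots of the same
#'   template).
#' @param target_density mean polymerases per gene.
#' @param footprint polymerase footprint, nt.
#' @param seed integer seed.
#' @return a [miller_spreads] object.
#' @export
simulate_miller_spreads <- function(model, n_genes, target_density = 50,
                                    footprint = 40, seed) {
  stopifnot(inherits(model, "pause_model"), n_genes >= 1)
  if (missing(seed)) stop("'seed' is required")
  L <- model$template$length
  if (target_density * footprint > L) {
    stop("infeasible density: target_density * footprint exceeds gene length")
  }
  h <- footprint / 2
  with_seed(seed, {
    genes <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      n_i <- stats::rpois(1L, target_density)
      acc <- numeric(0)
      if (n_i > 0L) {
        # Batched dwell-weighted draws; refill until n_i are accepted.
        draws <- sample.int(L, 4L * n_i + 16L, replace = TRUE,
                            prob = model$dwell)
        ptr <- 0L
        refills <- 0L
        while (length(acc) < n_i) {
          ptr <- ptr + 1L
          if (ptr > length(draws)) {
            refills <- refills + 1L
            if (refills > 200L) stop("placement failed; density too high")
            draws <- sample.int(L, 4L * n_i + 16L, replace = TRUE,
                                prob = model$dwell)
            ptr <- 1L
          }
          # Active-site coordinate at the center of the sampled nucleotide.
          x <- draws[ptr] - 0.5
          if (x < h || x > L - h) next
          if (length(acc) && any(abs(acc - x) < footprint)) next
          acc <- c(acc, x)
        }
      }
      genes[[g]] <- sort(acc)
    }
    names(genes) <- sprintf("gene_%04d", seq_len(n_genes))
    miller_spreads(genes, gene_length = L, footprint = footprint)
  })
}
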