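DEFAULT_ADAPTOR <- "ATCTCGTATGCCGTCTTCTGCTTG"

#' Simulate a synthetic NET-Seq library
#'
#' Draws `depth` reads from a [pause_model]. A deterministic
#' `round(contamination_frac * depth)` of them are mature-rRNA contaminants
#' whose 3' ends are uniform over mature-region positions (contamination is
#' confined to mature regions because spacers are degraded before mature
#' rRNA accumulates); the rest are nascent transcripts whose 3' ends are
#' sampled in proportion to dwell over the whole template. Each read is the
#' nontemplate-strand (RNA-like) substring of length `read_len` ending at
#' its 3' end, truncated at the TSS when the end is closer than `read_len`
#' (never padded). The raw record layout is `[UMI][insert][adaptor]` with a
#' random fixed-length UMI.
#'
#' @param model a [pause_model].
#' @param depth number of reads (> 0).
#' @param read_len nascent-fragment length in nt.
#' @param umi_len UMI length in nt.
#' @param adaptor 3' adaptor sequence appended to every record.
#' @param contamination_frac fraction of reads that are mature-rRNA
#'   contaminants, in `[0, 1]`.
#' @param seed integer seed; the library is deterministic given its inputs.
#' @param library_id,strain labels stored on the object (strain defaults to
#'   the model's).
#' @return object of class `netseq_sim`: `$reads` (`data.frame` with `id`,
#'   `record`), `$truth` (`id`, `true_end`, `is_contaminant`), plus the
#'   simulation parameters.
#' @examples
#' tpl <- make_default_template(seed = 1)
#' m <- build_pause_model(tpl, c(A = 2, C = 1, G = 2, T = 1))
#' sim <- simulate_netseq_library(m, depth = 1000, seed = 7)
#' nrow(sim$reads)  # 1000
#' @export
simulate_netseq_library <- function(model, depth, read_len = 40L,
                                    umi_len = 8L,
                                    adaptor = DEFAULT_ADAPTOR,
                                    contamination_frac = 0.1,
                                    seed,
                                    library_id = "lib1",
                                    strain = model$strain) {
  stopifnot(inherits(model, "pause_model"))
  depth <- as.integer(depth)
  if (is.na(depth) || depth <= 0L) stop("'depth' must be positive")
  stop_if_not_scalar_prob(contamination_frac, "contamination_frac")
  if (missing(seed)) stop("'seed' is required")
  tpl <- model$template
  L <- tpl$length
  n_cont <- as.integer(round(contamination_frac * depth))
  n_nasc <- depth - n_cont
  mature_pos <- if (n_cont > 0L) region_positions(tpl, "mature") else integer()

  with_seed(seed, {
    ends <- integer(depth)
    is_cont <- logical(depth)
    if (n_nasc > 0L) {
      ends[seq_len(n_nasc)] <- sample.int(L, n_nasc, replace = TRUE,
                                          prob = model$dwell)
    }
    if (n_cont > 0L) {
      ends[n_nasc + seq_len(n_cont)] <-
        mature_pos[sample.int(length(mature_pos), n_cont, replace = TRUE)]
      is_cont[n_nasc + seq_len(n_cont)] <- TRUE
    }
    ord <- sample.int(depth)
    ends <- ends[ord]
    is_cont <- is_cont[ord]
    starts <- pmax(1L, ends - read_len + 1L)
    inserts <- substring(tpl$sequence, starts, ends)
    umis <- random_seq(depth, umi_len)
    ids <- sprintf("read_%07d", seq_len(depth))
    structure(list(
      reads = data.frame(id = ids,
                         record = paste0(umis, inserts, adaptor),
                         stringsAsFactors = FALSE),
      truth = data.frame(id = ids, true_end = ends,
                         is_contaminant = is_cont,
                         stringsAsFactors = FALSE),
      template = tpl, depth = depth, read_len = as.integer(read_len),
      umi_len = as.integer(umi_len), adaptor = adaptor,
      contamination_frac = contamination_frac, seed = as.integer(seed),
      library_id = library_id, strain = strain),
      class = "netseq_sim")
  })
}

#' @export
print.netseq_sim <- function(x, ...) {
  cat(sprintf(
    "<netseq_sim> %s (%s): %d reads on %s; %.1f%% contaminant; seed %d\n",
    x$library_id, x$strain, x$depth, x$template$name,
    100 * mean(x$truth$is_contaminant), x$seed))
  invisible(x)
}

#' Occupancy profile from simulation ground truth
#'
#' Tabulates the true 3'-end positions of a simulated library into an
#' [occupancy_profile], bypassing read processing. Useful for statistical
#' analyses where mapper exactness has been established separately.
#'
#' @param sim a `netseq_sim`.
#' @param library_id,strain optional label overrides.
#' @return an [occupancy_profile] (normalized).
#' @export
as_profile <- function(sim, library_id = sim$library_id,
                       strain = sim$strain) {
  stopifnot(inherits(sim, "netseq_sim"))
  counts <- tabulate(sim$truth$true_end, nbins = sim$template$length)
  normalize_profile(occupancy_profile(
    counts, library_id = library_id, strain = strain,
    template_name = sim$template$name,
    stats = list(input_reads = sim$depth, dedup_removed = 0L,
                 no_adaptor = 0L, unmapped = 0L, ambiguous = 0L,
                 mapped = sim$depth)))
}
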