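# Large polymerase-free gap analysis of Miller chromatin spread data.
#
# Positions are active-site coordinates on [0, gene_length); a polymerase at
# position p occupies the footprint interval [p - footprint/2,
# p + footprint/2).

#' Polymerase-free gaps on one gene
#'
#' Gaps are the maximal polymerase-free intervals of the gene: from the
#' promoter (0) to the upstream edge of the first footprint, between
#' consecutive footprints, and from the last footprint to the gene end. A
#' gene with zero polymerases is one gap covering the whole gene. Gap
#' `start` is the promoter-proximal edge.
#'
#' @param gene_positions sorted numeric vector of active-site coordinates in
#'   `[0, gene_length)`.
#' @param gene_length gene length, nt.
#' @param footprint polymerase footprint, nt.
#' @return `data.frame` with columns `start`, `length`, `start_fraction`.
#' @examples
#' call_gaps(c(200, 500), 1000, footprint = 0)
#' @export
call_gaps <- function(gene_positions, gene_length, footprint = 40) {
  p <- as.numeric(gene_positions)
  if (is.unsorted(p)) stop("positions must be sorted")
  if (length(p) && (p[1] < 0 || p[length(p)] >= gene_length)) {
    stop("positions must lie in [0, gene_length)")
  }
  h <- footprint / 2
  if (!length(p)) {
    starts <- 0
    lens <- gene_length
  } else {
    starts <- c(0, p + h)
    ends <- c(p - h, gene_length)
    lens <- ends - starts
  }
  keep <- lens > 0
  df <- data.frame(start = pmax(0, starts[keep]), length = lens[keep])
  df$start_fraction <- df$start / gene_length
  df
}

#' Keep only large gaps
#'
#' A "large gap" is a polymerase-free stretch longer than
#' `threshold_fraction` of the gene: the default 0.25 corresponds to room
#' for ~40 packed polymerases (~25% of the gene); the alternative
#' experimental convention `> 23%` is available via
#' `threshold_fraction = 0.23`. The comparison is strict (`>`).
#'
#' @param gaps `data.frame` from [call_gaps()] (a `gene_id` column, if
#'   present, is preserved).
#' @param gene_length gene length, nt.
#' @param threshold_fraction in `(0, 1]`.
#' @return the subset of `gaps` with `length > threshold_fraction *
#'   gene_length`.
#' @export
large_gap_filter <- function(gaps, gene_length, threshold_fraction = 0.25) {
  if (!(threshold_fraction > 0 && threshold_fraction <= 1)) {
    stop("threshold_fraction must be in (0, 1]")
  }
  gaps[gaps$length > threshold_fraction * gene_length, , drop = FALSE]
}

#' Bin large-gap start positions along the gene
#'
#' Gap starts are binned by `floor(start_fraction * n_bins)` (clamped to the
#' last bin) over `n_bins` equal intervals of the gene - for a ~6.7 kb gene
#' and 10 bins, ~670 bp per bin - and frequencies are reported per scored
#' gene (or per gap when `n_genes` is not given), plotted at bin midpoints.
#' With threshold fraction t, no large gap can start beyond `1 - t` of the
#' gene, so 3'-terminal bins are structurally empty.
#'
#' @param large_gaps `data.frame` with a `start_fraction` column.
#' @param n_bins number of bins (>= 1).
#' @param n_genes number of genes scored, used as the frequency denominator;
#'   defaults to the number of gaps.
#' @return `data.frame` with columns `bin`, `midpoint_fraction`, `count`,
#'   `frequency`.
#' @export
bin_gap_starts <- function(large_gaps, n_bins = 10L, n_genes = NULL) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  idx <- pmin(floor(large_gaps$start_fraction * n_bins), n_bins - 1L) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  denom <- if (is.null(n_genes)) max(1L, nrow(large_gaps)) else n_genes
  data.frame(bin = seq_len(n_bins),
             midpoint_fraction = (seq_len(n_bins) - 0.5) / n_bins,
             count = counts,
             frequency = counts / denom)
}

#' Summarize large-gap frequency across a spread set
#'
#' The headline statistic is the fraction of genes with at least one large
#' gap (each gene counted once), the quantity reported for Miller-spread
#' surveys; the per-bin start-position frequencies accompany it.
#'
#' @param spreads a `miller_spreads` object (see
#'   [simulate_miller_spreads()] / [read_spreads_tsv()]).
#' @param threshold_fraction large-gap threshold, fraction of gene length.
#' @param n_bins bins for [bin_gap_starts()].
#' @return list of class `gap_summary`: `n_genes`,
#'   `n_genes_with_large_gap`, `fraction`, `bins`, `gaps` (per-gap table
#'   with `gene_id`).
#' @export
summarize_gap_frequency <- function(spreads, threshold_fraction = 0.25,
                                    n_bins = 10L) {
  stopifnot(inherits(spreads, "miller_spreads"))
  L <- spreads$gene_length
  per_gene <- lapply(seq_along(spreads$genes), function(i) {
    g <- call_gaps(spreads$genes[[i]], L, spreads$footprint)
    g <- large_gap_filter(g, L, threshold_fraction)
    if (nrow(g)) cbind(gene_id = names(spreads$genes)[i] %||%
                         sprintf("gene_%04d", i), g)
    else NULL
  })
  gaps <- do.call(rbind, per_gene)
  if (is.null(gaps)) {
    gaps <- data.frame(gene_id = character(), start = numeric(),
                       length = numeric(), start_fraction = numeric())
  }
  n_hit <- length(unique(gaps$gene_id))
  n_genes <- length(spreads$genes)
  structure(list(n_genes = n_genes,
                 n_genes_with_large_gap = n_hit,
                 fraction = n_hit / n_genes,
                 bins = bin_gap_starts(gaps, n_bins, n_genes = n_genes),
                 gaps = gaps,
                 threshold_fraction = threshold_fraction),
            class = "gap_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gap_summary <- function(x, ...) {
  cat(sprintf(
    "<gap_summary> %d/%d genes (%.1f%%) with a gap > %.0f%% of gene length\n",
    x$n_genes_with_large_gap, x$n_genes, 100 * x$fraction,
    100 * x$threshold_fraction))
  invisible(x)
}

#' Read / write Miller-spread position lists
#'
#' TSV interchange format: columns `gene_id`, `positions` (comma-separated
#' active-site coordinates) and `gene_length`; the polymerase footprint is
#' recorded as a `# footprint=` header line.
#'
#' @param path TSV path.
#' @return `read_spreads_tsv`: a `miller_spreads` object.
#' @export
read_spreads_tsv <- function(path) {
  hdr <- readLines(path, n = 5L)
  fp <- hdr[startsWith(hdr, "# footprint=")]
  footprint <- if (length(fp)) as.numeric(sub("# footprint=", "", fp[1])) else 40
  df <- read_tsv_meta(path)
  genes <- lapply(strsplit(as.character(df$positions), ","), function(x) {
    sort(as.numeric(x[nzchar(x)]))
  })
  names(genes) <- df$gene_id
  miller_spreads(genes, gene_length = df$gene_length[1],
                 footprint = footprint)
}

#' @rdname read_spreads_tsv
#' @param spreads a `miller_spreads` object.
#' @export
write_spreads_tsv <- function(spreads, path) {
  stopifnot(inherits(spreads, "miller_spreads"))
  df <- data.frame(
    gene_id = names(spreads$genes),
    positions = vapply(spreads$genes, paste, character(1), collapse = ","),
    gene_length = spreads$gene_length)
  write_tsv_meta(df, path, c(footprint = as.character(spreads$footprint)))
}

#' Miller-spread container
#'
#' @param genes named list of sorted polymerase position vectors
#'   (active-site coordinates in `[0, gene_length)`).
#' @param gene_length gene length, nt.
#' @param footprint polymerase footprint, nt; consecutive positions within
#'   a gene must differ by at least this.
#' @return object of class `miller_spreads`.
#' @export
miller_spreads <- function(genes, gene_length, footprint = 40) {
  stopifnot(is.list(genes), gene_length > 0, footprint >= 0)
  for (g in genes) {
    if (is.unsorted(g)) stop("gene positions must be sorted")
    if (length(g) > 1L && any(diff(g) < footprint)) {
      stop("positions closer than the footprint")
    }
  }
  if (is.null(names(genes))) {
    names(genes) <- sprintf("gene_%04d", seq_along(genes))
  }
  structure(list(genes = genes, gene_length = as.numeric(gene_length),
                 footprint = as.numeric(footprint)),
            class = "miller_spreads")
}
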