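#' Per-position 3'-end occupancy profile
#'
#' Holds per-position counts of last-incorporated-nucleotide (3'-end)
#' positions for one library, together with read-accounting statistics. The
#' accounting identity
#' `input_reads = dedup_removed + no_adaptor + unmapped + ambiguous + mapped`
#' holds for every profile produced by [process_library()].
#'
#' @param counts non-negative integer vector, one element per template
#'   position.
#' @param library_id,strain library labels.
#' @param stats named list with elements `input_reads`, `dedup_removed`,
#'   `no_adaptor`, `unmapped`, `ambiguous`, `mapped`; `mapped` must equal
#'   `sum(counts)`.
#' @param template_name name of the template the profile is on.
#' @return object of class `occupancy_profile` with elements `counts`,
#'   `normalized` (`NULL` until [normalize_profile()] is applied),
#'   `stats`, `library_id`, `strain`, `template_name`.
#' @export
occupancy_profile <- function(counts, library_id, strain = NA_character_,
                              stats = NULL, template_name = NA_character_) {
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 0L)) {
    stop("counts must be non-negative integers")
  }
  if (is.null(stats)) {
    n <- sum(counts)
    stats <- list(input_reads = n, dedup_removed = 0L, no_adaptor = 0L,
                  unmapped = 0L, ambiguous = 0L, mapped = n)
  }
  req <- c("input_reads", "dedup_removed", "no_adaptor", "unmapped",
           "ambiguous", "mapped")
  if (!all(req %in% names(stats))) {
    stop("stats must contain: ", paste(req, collapse = ", "))
  }
  if (stats$mapped != sum(counts)) {
    stop("stats$mapped must equal sum(counts)")
  }
  structure(list(counts = counts, normalized = NULL, stats = stats,
                 library_id = library_id, strain = strain,
                 template_name = template_name),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<occupancy_profile> %s (%s) on %s: %d positions, %d mapped reads\n",
    x$library_id, x$strain, x$template_name, length(x$counts), s$mapped))
  cat(sprintf(
    "  accounting: input=%d dedup_removed=%d no_adaptor=%d unmapped=%d ambiguous=%d\n",
    s$input_reads, s$dedup_removed, s$no_adaptor, s$unmapped, s$ambiguous))
  invisible(x)
}

#' Remove UMI duplicates
#'
#' Among reads with an identical raw record (UMI plus full insert sequence),
#' only the first encountered survives; read order is otherwise preserved.
#' Applied before trimming and mapping, mirroring sequence-level
#' deduplication ahead of alignment.
#'
#' @param reads `data.frame` with columns `id`, `record`.
#' @param umi_len expected UMI length; reads shorter than this are an error.
#' @return list with `reads` (survivors) and `removed` (count).
#' @export
deduplicate_umis <- function(reads, umi_len) {
  stopifnot(is.data.frame(reads), all(c("id", "record") %in% names(reads)))
  if (any(nchar(reads$record) < umi_len)) {
    stop("read shorter than the configured UMI length")
  }
  keep <- !duplicated(reads$record)
  list(reads = reads[keep, , drop = FALSE], removed = sum(!keep))
}

#' Split off the UMI and trim the 3' adaptor
#'
#' The UMI is split off as the first `umi_len` bases of the record. The
#' longest suffix of the remaining sequence that exactly matches a prefix of
#' the adaptor, with overlap at least `min_overlap`, is removed. Reads with
#' no qualifying adaptor match are discarded (and counted), since a missing
#' adaptor means the 3' end - the last incorporated nucleotide - cannot be
#' located reliably.
#'
#' @param reads `data.frame` with columns `id`, `record`.
#' @param adaptor adaptor sequence (non-empty).
#' @param umi_len UMI length.
#' @param min_overlap minimum adaptor overlap (>= 1).
#' @return list with `reads` (`data.frame` of `id`, `umi`, `insert`) and
#'   `discarded` (count of reads without an adaptor match).
#' @export
trim_adaptor <- function(reads, adaptor, umi_len, min_overlap = 5L) {
  stopifnot(is.data.frame(reads), nzchar(adaptor), min_overlap >= 1L)
  n_in <- nrow(reads)
  len <- nchar(reads$record)
  if (any(len < umi_len)) stop("read shorter than the configured UMI length")
  umi <- substr(reads$record, 1L, umi_len)
  rest <- substr(reads$record, umi_len + 1L, len)
  rlen <- nchar(rest)
  trim_len <- rep(NA_integer_, n_in)
  max_l <- min(nchar(adaptor), if (n_in) max(rlen) else 0L)
  if (max_l >= min_overlap) {
    for (L in seq.int(max_l, min_overlap, by = -1L)) {
      open <- which(is.na(trim_len) & rlen >= L)
      if (!length(open)) break
      hit <- substr(rest[open], rlen[open] - L + 1L, rlen[open]) ==
        substr(adaptor, 1L, L)
      trim_len[open[hit]] <- L
    }
  }
  kept <- which(!is.na(trim_len))
  out <- data.frame(id = reads$id[kept],
                    umi = umi[kept],
                    insert = substr(rest[kept], 1L,
                                    rlen[kept] - trim_len[kept]),
                    stringsAsFactors = FALSE)
  list(reads = out, discarded = n_in - length(kept))
}

#' Map trimmed reads to the template by their 3'-terminal k-mer
#'
#' Exact single-locus mapper preserving the last-incorporated-nucleotide
#' position: each read's 3'-terminal `min_match`-mer is looked up on the
#' template's nontemplate strand. A read whose terminal k-mer occurs more
#' than once on the template is ambiguous and discarded; a unique hit is
#' accepted only if the full read matches the template substring ending at
#' the hit (reads extending upstream past the TSS are unmapped). Reads
#' shorter than `min_match` are unmapped. Counts are incremented at the
#' template position aligned to the read's 3' end.
#'
#' @param trimmed `data.frame` with columns `id`, `insert` (from
#'   [trim_adaptor()]).
#' @param template an [rdna_template].
#' @param min_match terminal k-mer length (>= 12; exact matching only).
#' @param library_id,strain labels for the resulting profile.
#' @param prior_stats optional partial accounting list (`input_reads`,
#'   `dedup_removed`, `no_adaptor`) carried in from earlier stages.
#' @return an [occupancy_profile] (not yet normalized), with a per-read
#'   assignment table in `attr(, "assignments")` (`id`, `position`,
#'   `status`).
#' @export
map_three_prime_ends <- function(trimmed, template, min_match = 18L,
                                 library_id = "lib", strain = NA_character_,
                                 prior_stats = NULL) {
  stopifnot(inherits(template, "rdna_template"))
  k <- as.integer(min_match)
  if (k < 12L) stop("min_match must be >= 12")
  L <- template$length
  if (k > L) stop("min_match longer than the template")
  starts <- seq_len(L - k + 1L)
  tkmers <- substring(template$sequence, starts, starts + k - 1L)
  dup_kmers <- unique(tkmers[duplicated(tkmers)])
  kmer_end <- starts + k - 1L

  n <- nrow(trimmed)
  status <- rep("unmapped", n)
  position <- rep(NA_integer_, n)
  ilen <- nchar(trimmed$insert)
  cand <- which(ilen >= k)
  if (length(cand)) {
    rk <- substr(trimmed$insert[cand], ilen[cand] - k + 1L, ilen[cand])
    amb <- rk %in% dup_kmers
    status[cand[amb]] <- "ambiguous"
    uniq <- cand[!amb]
    m <- match(rk[!amb], tkmers)
    hit <- !is.na(m)
    uniq <- uniq[hit]
    if (length(uniq)) {
      pos <- kmer_end[m[hit]]
      st <- pos - ilen[uniq] + 1L
      ok <- st >= 1L
      if (any(ok)) {
        ok[ok] <- substring(template$sequence, st[ok], pos[ok]) ==
          trimmed$insert[uniq[ok]]
      }
      status[uniq[ok]] <- "mapped"
      position[uniq[ok]] <- pos[ok]
    }
  }
  counts <- tabulate(position[status == "mapped"], nbins = L)
  stats <- list(input_reads = n, dedup_removed = 0L, no_adaptor = 0L,
                unmapped = sum(status == "unmapped"),
                ambiguous = sum(status == "ambiguous"),
                mapped = sum(status == "mapped"))
  if (!is.null(prior_stats)) {
    stats$input_reads <- prior_stats$input_reads
    stats$dedup_removed <- prior_stats$dedup_removed
    stats$no_adaptor <- prior_stats$no_adaptor
  }
  prof <- occupancy_profile(counts, library_id = library_id, strain = strain,
                            stats = stats, template_name = template$name)
  attr(prof, "assignments") <- data.frame(id = trimmed$id,
                                          position = position,
                                          status = status,
                                          stringsAsFactors = FALSE)
  prof
}

#' Depth-normalize an occupancy profile
#'
#' Normalization is counts per million template-mapped reads (CPM over the
#' template): `normalized = counts * 1e6 / sum(counts)`.
#'
#' @param profile an [occupancy_profile] with at least one mapped read.
#' @return the profile with `$normalized` filled in.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "occupancy_profile"))
  total <- sum(profile$counts)
  if (total == 0L) stop("cannot normalize an all-zero profile")
  profile$normalized <- profile$counts * 1e6 / total
  profile
}

#' Run the full read-processing pipeline on one library
#'
#' Deduplicate (UMI + insert) -> split UMI and trim the 3' adaptor -> map
#' 3'-terminal k-mers to the template -> CPM-normalize. The accounting
#' identity over all stages is preserved in the profile's `stats`.
#'
#' @param reads `data.frame` with columns `id`, `record` (from
#'   [read_fastq()] or a `netseq_sim`'s `$reads`).
#' @param template an [rdna_template].
#' @param umi_len,adaptor,min_overlap,min_match stage parameters; see
#'   [trim_adaptor()] and [map_three_prime_ends()].
#' @param library_id,strain labels for the profile.
#' @return a normalized [occupancy_profile].
#' @examples
#' tpl <- make_default_template(seed = 1)
#' m <- build_pause_model(tpl, c(A = 2, C = 1, G = 2, T = 1))
#' sim <- simulate_netseq_library(m, depth = 2000, seed = 3)
#' prof <- process_library(sim$reads, tpl, umi_len = 8,
#'                         adaptor = sim$adaptor)
#' prof$stats$mapped
#' @export
process_library <- function(reads, template, umi_len = 8L,
                            adaptor = DEFAULT_ADAPTOR, min_overlap = 5L,
                            min_match = 18L, library_id = "lib",
                            strain = NA_character_) {
  n_input <- nrow(reads)
  dd <- deduplicate_umis(reads, umi_len)
  tr <- trim_adaptor(dd$reads, adaptor, umi_len, min_overlap)
  prof <- map_three_prime_ends(
    tr$reads, template, min_match, library_id = library_id, strain = strain,
    prior_stats = list(input_reads = n_input, dedup_removed = dd$removed,
                       no_adaptor = tr$discarded))
  normalize_profile(prof)
}

#' Export an occupancy profile
#'
#' `write_profile_tsv` writes one row per position with columns
#' `position` (1-based), `region`, `base`, `count`, `normalized`;
#' `write_profile_bedgraph` writes nonzero counts 0-based half-open;
#' `write_stats_report` writes the read-accounting as `key<TAB>value` lines.
#'
#' @param profile a normalized [occupancy_profile].
#' @param template the [rdna_template] the profile was mapped to.
#' @param path output path.
#' @param meta optional named character vector of metadata, written as
#'   `# key=value` header lines.
#' @return invisibly, `path`.
#' @export
write_profile_tsv <- function(profile, template, path, meta = character()) {
  stopifnot(inherits(profile, "occupancy_profile"),
            inherits(template, "rdna_template"),
            !is.null(profile$normalized))
  pos <- seq_len(template$length)
  idx <- findInterval(pos, template$regions$start)
  df <- data.frame(position = pos,
                   region = template$regions$name[idx],
                   base = seq_chars(template$sequence),
                   count = profile$counts,
                   normalized = profile$normalized,
                   stringsAsFactors = FALSE)
  write_tsv_meta(df, path,
                 c(library_id = profile$library_id,
                   strain = as.character(profile$strain),
                   template = template$name,
                   mapped = as.character(profile$stats$mapped), meta))
}

#' Read back a profile TSV written by [write_profile_tsv()]
#'
#' @param path profile TSV path.
#' @return a normalized [occupancy_profile]; library and strain labels are
#'   recovered from the header lines.
#' @export
read_profile_tsv <- function(path) {
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "# ")]
  kv <- sub("^# ", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(vals, keys)
  df <- read_tsv_meta(path)
  prof <- occupancy_profile(df$count,
                            library_id = meta[["library_id"]],
                            strain = meta[["strain"]],
                            template_name = meta[["template"]])
  normalize_profile(prof)
}

#' @rdname write_profile_tsv
#' @export
write_profile_bedgraph <- function(profile, template, path,
                                   meta = character()) {
  stopifnot(inherits(profile, "occupancy_profile"))
  nz <- which(profile$counts > 0L)
  df <- data.frame(chrom = template$name, start = nz - 1L, end = nz,
                   count = profile$counts[nz])
  con <- file(path, "wt")
  on.exit(close(con), add = TRUE)
  if (length(meta)) writeLines(paste0("# ", names(meta), "=", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
write_stats_report <- function(profile, path, meta = character()) {
  stopifnot(inherits(profile, "occupancy_profile"))
  s <- profile$stats
  lines <- c(if (length(meta)) paste0("# ", names(meta), "=", meta),
             paste(names(s), unlist(s), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
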