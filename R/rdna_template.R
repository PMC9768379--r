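#' rDNA transcription-unit template
#'
#' An `rdna_template` represents a single Pol I transcription unit (the 35S
#' precursor in yeast): the nontemplate-strand (RNA-like) sequence plus an
#' ordered annotation of regions classed as `"spacer"` (external/internal
#' transcribed spacers, removed during rRNA processing) or `"mature"`
#' (18S/5.8S/25S, retained in the ribosome and therefore subject to
#' mature-rRNA contamination in NET-Seq libraries).
#'
#' Coordinates in the R API are 1-based and closed (position 1 is the
#' transcription start site, +1). On disk, region tables are stored BED-like,
#' 0-based half-open.
#'
#' @param name template name.
#' @param sequence nontemplate-strand sequence, characters in `A,C,G,T` only.
#'   Other characters (including IUPAC ambiguity codes) are rejected, because
#'   downstream position-weight-matrix arithmetic assumes a 4-letter alphabet.
#' @param regions `data.frame` with columns `name`, `start`, `end` (1-based,
#'   closed) and `cls` (`"spacer"` or `"mature"`). Regions must tile the
#'   template exactly, without overlap or gaps.
#' @return an object of class `rdna_template` with elements `name`,
#'   `sequence`, `length` and `regions`.
#' @examples
#' tpl <- rdna_template("toy", strrep("ACGT", 25),
#'   data.frame(name = c("ETS1", "18S"), start = c(1, 41), end = c(40, 100),
#'              cls = c("spacer", "mature")))
#' tpl$length
#' @export
rdna_template <- function(name, sequence, regions) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 1L) stop("template sequence is empty")
  bad <- gsub("[ACGT]", "", sequence)
  if (nzchar(bad)) {
    stop(sprintf("sequence contains non-ACGT characters: '%s'",
                 substr(bad, 1, 10)))
  }
  req <- c("name", "start", "end", "cls")
  if (!is.data.frame(regions) || !all(req %in% names(regions))) {
    stop("'regions' must be a data.frame with columns name, start, end, cls")
  }
  regions <- regions[order(regions$start), req, drop = FALSE]
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  regions$name <- as.character(regions$name)
  regions$cls <- as.character(regions$cls)
  if (!all(regions$cls %in% c("spacer", "mature"))) {
    stop("region cls must be 'spacer' or 'mature'")
  }
  if (any(regions$start > regions$end) || any(regions$start < 1L) ||
      any(regions$end > L)) {
    stop("region bounds must satisfy 1 <= start <= end <= template length")
  }
  expected <- 1L
  for (i in seq_len(nrow(regions))) {
    if (regions$start[i] > expected) {
      stop(sprintf("region coverage gap at position %d", expected))
    }
    if (regions$start[i] < expected) {
      stop(sprintf("overlapping regions at position %d", regions$start[i]))
    }
    expected <- regions$end[i] + 1L
  }
  if (expected != L + 1L) {
    stop(sprintf("region coverage gap at position %d", expected))
  }
  structure(list(name = name, sequence = sequence, length = L,
                 regions = regions),
            class = "rdna_template")
}

#' @export
print.rdna_template <- function(x, ...) {
  cat(sprintf("<rdna_template> %s: %d nt, %d regions (%d spacer, %d mature)\n",
              x$name, x$length, nrow(x$regions),
              sum(x$regions$cls == "spacer"), sum(x$regions$cls == "mature")))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' @export
length.rdna_template <- function(x) x$length

# Default 35S-like region layout. Lengths are synthetic, plausible yeast-like
# values chosen so the total is 6,700 nt (one 10% bin = 670 bp).
DEFAULT_REGION_LENGTHS <- c(ETS1 = 700L, `18S` = 1800L, ITS1 = 360L,
                            `5.8S` = 160L, ITS2 = 230L, `25S` = 3050L,
                            ETS2 = 400L)
DEFAULT_REGION_CLASSES <- c("spacer", "mature", "spacer", "mature",
                            "spacer", "mature", "spacer")

#' Build the default synthetic rDNA template
#'
#' Generates a deterministic pseudo-random 35S-like transcription unit with
#' the canonical region order ETS1, 18S, ITS1, 5.8S, ITS2, 25S, ETS2 (spacers
#' ETS1/ITS1/ITS2/ETS2, mature 18S/5.8S/25S). The default total length is
#' 6,700 nt, so that 10%-of-gene bins used in Miller-spread gap analysis are
#' 670 bp. The sequence is synthetic: region lengths and base composition are
#' plausible yeast-like choices, not database coordinates.
#'
#' The first `cless_leader` positions are drawn from `A,G,T` only and the
#' next position is forced to `C`, reproducing the structure of the initially
#' transcribed region of the rDNA in which elongation complexes synchronize
#' at the first encoded C residue (+56) when CTP is withheld.
#'
#' @param seed integer seed; the same seed always yields the same template.
#' @param region_lengths named integer vector of region lengths, in template
#'   order. Names become region names.
#' @param region_classes character vector (`"spacer"`/`"mature"`) matching
#'   `region_lengths`.
#' @param gc GC fraction used to draw the sequence; either a single value or
#'   one value per region.
#' @param cless_leader length of the 5' C-less leader (0 disables it).
#' @param name template name.
#' @return an [rdna_template].
#' @examples
#' tpl <- make_default_template(seed = 1)
#' tpl$length  # 6700
#' first_c_position(tpl)  # 56
#' @export
make_default_template <- function(seed = 1L,
                                  region_lengths = DEFAULT_REGION_LENGTHS,
                                  region_classes = DEFAULT_REGION_CLASSES,
                                  gc = 0.5,
                                  cless_leader = 55L,
                                  name = "rDNA_35S_synthetic") {
  stopifnot(length(region_lengths) == length(region_classes),
            all(region_lengths > 0))
  if (length(gc) == 1L) gc <- rep(gc, length(region_lengths))
  stopifnot(length(gc) == length(region_lengths), all(gc > 0 & gc < 1))
  total <- sum(region_lengths)
  if (cless_leader >= total) stop("cless_leader exceeds template length")
  seqs <- with_seed(seed, {
    mapply(function(len, g) {
      p <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)
      random_seq(1L, len, p)
    }, region_lengths, gc)
  })
  sequence <- paste(seqs, collapse = "")
  if (cless_leader > 0L) {
    # Re-draw the leader without C, then force the first C at leader + 1.
    leader <- with_seed(seed + 1L, {
      paste(sample(c("A", "G", "T"), cless_leader, replace = TRUE),
            collapse = "")
    })
    sequence <- paste0(leader, "C",
                       substr(sequence, cless_leader + 2L, total))
  }
  ends <- cumsum(as.integer(region_lengths))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  regions <- data.frame(name = names(region_lengths), start = starts,
                        end = ends, cls = region_classes,
                        stringsAsFactors = FALSE)
  rdna_template(name, sequence, regions)
}

#' Load an rDNA template from FASTA + region table
#'
#' @param fasta_path single-record FASTA file with the nontemplate-strand
#'   sequence.
#' @param regions_path TSV with columns `name`, `start`, `end`, `cls`;
#'   coordinates 0-based half-open (BED convention).
#' @return an [rdna_template].
#' @seealso [write_template()]
#' @export
load_template <- function(fasta_path, regions_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) != 1L) {
    stop(sprintf("FASTA must contain exactly one record, found %d",
                 length(ss)))
  }
  reg <- utils::read.delim(regions_path, stringsAsFactors = FALSE)
  req <- c("name", "start", "end", "cls")
  if (!all(req %in% names(reg))) {
    stop("regions table must have columns name, start, end, cls")
  }
  reg$start <- reg$start + 1L  # 0-based half-open -> 1-based closed
  rdna_template(sub("\\s.*$", "", names(ss)[1]),
                as.character(ss[[1]]), reg)
}

#' Write an rDNA template to FASTA + region table
#'
#' Inverse of [load_template()]; region coordinates are written 0-based
#' half-open.
#'
#' @param template an [rdna_template].
#' @param fasta_path,regions_path output paths.
#' @return invisibly, the two paths.
#' @export
write_template <- function(template, fasta_path, regions_path) {
  stopifnot(inherits(template, "rdna_template"))
  ss <- Biostrings::DNAStringSet(template$sequence)
  names(ss) <- template$name
  Biostrings::writeXStringSet(ss, fasta_path)
  out <- template$regions
  out$start <- out$start - 1L  # 1-based closed -> 0-based half-open
  utils::write.table(out, regions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, regions_path))
}

#' Region containing a template position
#'
#' @param template an [rdna_template].
#' @param position 1-based position in `[1, length]`.
#' @return one-row `data.frame` (the containing region).
#' @export
region_of <- function(template, position) {
  stopifnot(inherits(template, "rdna_template"))
  position <- as.integer(position)
  if (any(position < 1L | position > template$length)) {
    stop("position out of range")
  }
  idx <- findInterval(position, template$regions$start)
  template$regions[idx, , drop = FALSE]
}

#' Positions belonging to regions of a given class or name
#'
#' @param template an [rdna_template].
#' @param regions character vector of region names, or one of the classes
#'   `"spacer"` / `"mature"`.
#' @return sorted integer vector of 1-based positions.
#' @export
region_positions <- function(template, regions = "spacer") {
  stopifnot(inherits(template, "rdna_template"))
  tab <- template$regions
  if (length(regions) == 1L && regions %in% c("spacer", "mature")) {
    tab <- tab[tab$cls == regions, , drop = FALSE]
  } else {
    miss <- setdiff(regions, tab$name)
    if (length(miss)) stop("unknown region(s): ", paste(miss, collapse = ", "))
    tab <- tab[tab$name %in% regions, , drop = FALSE]
  }
  if (!nrow(tab)) stop("no matching regions")
  sort(unlist(mapply(seq.int, tab$start, tab$end, SIMPLIFY = FALSE)))
}

#' First encoded C residue at or after a position
#'
#' In vitro, transcription without CTP synchronizes elongation complexes at
#' the first C encoded on the nontemplate strand; on the native initially
#' transcribed sequence this is position +56 (a 55-nt C-less leader).
#'
#' @param template an [rdna_template].
#' @param from_pos 1-based position to start searching from.
#' @return 1-based TSS-relative position of the first C, or `NA_integer_` if
#'   the template encodes no C at or after `from_pos`.
#' @export
first_c_position <- function(template, from_pos = 1L) {
  stopifnot(inherits(template, "rdna_template"))
  from_pos <- max(1L, as.integer(from_pos))
  if (from_pos > template$length) return(NA_integer_)
  tail_seq <- substr(template$sequence, from_pos, template$length)
  hit <- regexpr("C", tail_seq, fixed = TRUE)
  if (hit < 0L) return(NA_integer_)
  from_pos + as.integer(hit) - 1L
}
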