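#' Write a simulated library as FASTQ
#'
#' Records are written phred-33 with constant quality `"I"` (the simulator
#' does not model base-call error).
#'
#' @param sim a `netseq_sim` from [simulate_netseq_library()].
#' @param path output FASTQ path.
#' @return invisibly, `path`.
#' @export
write_netseq_fastq <- function(sim, path) {
  stopifnot(inherits(sim, "netseq_sim"))
  write_fastq(sim$reads, path)
}

#' Read/write raw reads as FASTQ
#'
#' Minimal FASTQ interface used by the pipeline: reads come back as a
#' `data.frame` of record id and sequence; qualities are not retained (all
#' downstream processing is sequence-exact).
#'
#' @param path FASTQ file path.
#' @return `read_fastq`: `data.frame` with columns `id`, `record`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(ss)),
             record = as.character(ss),
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads `data.frame` with columns `id`, `record`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "record") %in% names(reads)))
  ss <- Biostrings::DNAStringSet(reads$record)
  names(ss) <- reads$id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$record)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}
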