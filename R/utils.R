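# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that package functions with a `seed`
#' argument do not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1]]
}

# Random nucleotide string(s); p is a length-4 probability vector over ACGT.
random_seq <- function(n, len, p = rep(0.25, 4)) {
  m <- matrix(sample(BASES, n * len, replace = TRUE, prob = p),
              nrow = n, ncol = len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Write a data frame as TSV with '#'-prefixed metadata header lines.
write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (length(meta)) {
    writeLines(paste0("# ", names(meta), "=", unname(meta)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
}
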