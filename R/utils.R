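#' Translate CDR3 nucleotide sequences
#'
#' Standard-genetic-code translation in frame 1. Stops are reported as `*`;
#' a trailing partial codon (length not a multiple of 3) is reported as `_`,
#' the conventional frameshift marker.
#'
#' @param nt character vector of uppercase ACGT sequences.
#' @return character vector of amino-acid sequences.
#' @export
translate_cdr3 <- function(nt) {
  code <- Biostrings::GENETIC_CODE
  vapply(nt, function(s) {
    n <- nchar(s)
    n3 <- n %/% 3L
    if (n3 == 0L) return("_")
    codons <- substring(s, 3L * seq_len(n3) - 2L, 3L * seq_len(n3))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    paste0(paste(aa, collapse = ""), if (n %% 3L != 0L) "_" else "")
  }, character(1L), USE.NAMES = FALSE)
}

# Derive independent sub-seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Format numerics with 10 significant digits for TSV output (stable,
# round-trips freq sums to within 1e-8).
format_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], format_num)
  ok <- try(utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA"), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop(sprintf("failed to write '%s': %s", path, attr(ok, "condition")$message),
         call. = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
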