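# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# positions where two equal-length strings differ
#' @noRd
hamming_positions <- function(a, b) {
  which(utf8ToInt(a) != utf8ToInt(b))
}

#' @noRd
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("seed must be coercible to integer")
    set.seed(seed)
  }
  invisible(seed)
}

# stable content hash of a configuration list (provenance tag in outputs)
#' @noRd
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
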