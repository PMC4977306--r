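#' Normalize a nucleotide sequence to the uppercase DNA alphabet
#'
#' Uppercases and converts U to T. All internal sequence handling in halomir
#' is on the DNA alphabet; mature miRNAs may be printed with U on output.
#'
#' @param x character vector of sequences.
#' @return character vector, uppercase with U replaced by T.
#' @export
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Print a DNA sequence as RNA
#'
#' @param x character vector of DNA sequences.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse complement of a DNA sequence
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Hamming distance between two equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

## stop() with a consistent invalid-argument prefix
invalid_arg <- function(...) stop("invalid argument: ", ..., call. = FALSE)
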