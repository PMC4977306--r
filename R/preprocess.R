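#' Read small-RNA reads from FASTA or FASTQ
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] returning the plain
#' data frame of reads used throughout the preprocess stage. Sequences are
#' normalized to the uppercase DNA alphabet (U to T) at ingest.
#'
#' @param path path to a FASTA or 4-line Phred+33 FASTQ file.
#' @return a data frame with columns `id`, `sequence`, and for FASTQ
#'   `quality`.
#' @export
read_reads_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  data.frame(id = names(x), sequence = normalize_dna(as.character(x)),
             quality = NA_character_, row.names = NULL)
}

#' @rdname read_reads_fasta
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x), sequence = normalize_dna(as.character(x)),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL)
}

.as_reads <- function(reads) {
  if (is.character(reads))
    reads <- data.frame(id = if (length(reads)) paste0("read", seq_along(reads))
                             else character(),
                        sequence = reads,
                        quality = rep(NA_character_, length(reads)))
  if (!is.data.frame(reads) || !all(c("id", "sequence") %in% names(reads)))
    invalid_arg("'reads' must be a character vector or a data frame with id/sequence")
  if (is.null(reads$quality)) reads$quality <- NA_character_
  reads$sequence <- normalize_dna(reads$sequence)
  reads
}

#' Trim a 3' sequencing adapter from small-RNA reads
#'
#' Truncates each read at the leftmost position where a prefix of the adapter
#' of at least `min_overlap` bases matches exactly. Reads without any such
#' occurrence are returned unchanged. Trimming is exact-match and 3'-only;
#' mismatch-tolerant trimming is out of scope.
#'
#' @param reads a character vector of sequences or a reads data frame from
#'   [read_reads_fastq()] / [read_reads_fasta()].
#' @param adapter the 3' adapter sequence (non-empty).
#' @param min_overlap minimum exact adapter-prefix overlap required to trim
#'   (default 6; must satisfy `1 <= min_overlap <= nchar(adapter)`).
#' @return the reads in the same shape as the input, truncated; qualities are
#'   truncated alongside sequences.
#' @examples
#' trim_adapter(paste0("TGACAGAAGAGAGTGAGCAC", "TGGAATTC"), "TGGAATTCTCGG")
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  if (missing(adapter) || length(adapter) != 1L || is.na(adapter) ||
      nchar(adapter) == 0L)
    invalid_arg("'adapter' must be a non-empty string")
  adapter <- normalize_dna(adapter)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L || min_overlap > nchar(adapter))
    invalid_arg("need adapter length >= min_overlap >= 1")
  chr_in <- is.character(reads)
  reads <- .as_reads(reads)
  alen <- nchar(adapter)
  cut <- vapply(reads$sequence, function(s) {
    n <- nchar(s)
    for (i in seq_len(n)) {
      L <- min(alen, n - i + 1L)
      if (L < min_overlap) break
      if (substr(s, i, i + L - 1L) == substr(adapter, 1L, L)) return(i - 1L)
    }
    n
  }, integer(1), USE.NAMES = FALSE)
  reads$sequence <- substr(reads$sequence, 1L, cut)
  has_q <- !is.na(reads$quality)
  reads$quality[has_q] <- substr(reads$quality[has_q], 1L, cut[has_q])
  if (chr_in) reads$sequence else reads
}

#' Filter cleaned small-RNA reads by length, ambiguity and contamination
#'
#' Keeps exactly the reads with length inside `[min_len, max_len]`, no
#' ambiguous base (anything outside A/C/G/T), and no exact full-sequence
#' match to a contaminant (t/rRNA) set. Input order is preserved; the filter
#' is idempotent.
#'
#' @param reads character vector or reads data frame (adapter-trimmed).
#' @param contaminants character vector of contaminant sequences (or a
#'   `DNAStringSet`); matching is exact full-tag membership.
#' @param min_len,max_len retained length range (defaults 18 and 25 nt).
#' @return the surviving reads, same shape as the input.
#' @export
filter_reads <- function(reads, contaminants = character(), min_len = 18L,
                         max_len = 25L) {
  chr_in <- is.character(reads)
  reads <- .as_reads(reads)
  contaminants <- normalize_dna(as.character(contaminants))
  len <- nchar(reads$sequence)
  keep <- len >= min_len & len <= max_len &
    !grepl("[^ACGT]", reads$sequence) &
    !(reads$sequence %in% contaminants)
  out <- reads[keep, , drop = FALSE]
  row.names(out) <- NULL
  if (chr_in) out$sequence else out
}

#' Collapse clean reads into unique tags with per-library counts
#'
#' One tag per distinct sequence; the sum of tag counts per library equals
#' that library's clean read total. Alongside the tag table, a per-library
#' profile is computed: redundant and unique size histograms over 18–25 nt
#' and the 5'-nucleotide composition by length (fractions of unique tags).
#'
#' @param reads_by_library a named list, one element per library, each a
#'   character vector of clean sequences or a reads data frame.
#' @return a list with elements
#'   \describe{
#'     \item{tags}{data frame with `sequence` plus one integer count column
#'       per library (named as the list).}
#'     \item{profiles}{named list of `library_profile` lists with
#'       `library_id`, `total_clean_reads`, `redundant_size_histogram`,
#'       `unique_size_histogram`, `first_nt_by_length` (rows sum to 1).}
#'   }
#' @export
collapse_tags <- function(reads_by_library) {
  if (!is.list(reads_by_library) || is.null(names(reads_by_library)) ||
      any(names(reads_by_library) == ""))
    invalid_arg("'reads_by_library' must be a named list of libraries")
  seqs <- lapply(reads_by_library, function(r) .as_reads(r)$sequence)
  all_tags <- sort(unique(unlist(seqs, use.names = FALSE)))
  tags <- data.frame(sequence = all_tags)
  for (lib in names(seqs)) {
    tab <- table(factor(seqs[[lib]], levels = all_tags))
    tags[[lib]] <- as.integer(tab)
  }
  profiles <- lapply(names(seqs), function(lib) {
    s <- seqs[[lib]]
    lens <- 18:25
    red <- table(factor(nchar(s), levels = lens))
    u <- all_tags[tags[[lib]] > 0]
    uni <- table(factor(nchar(u), levels = lens))
    first <- matrix(0, length(lens), 4, dimnames = list(lens, c("A", "C", "G", "U")))
    for (L in lens) {
      uL <- u[nchar(u) == L]
      if (length(uL) == 0) next
      nt <- table(factor(substr(uL, 1, 1), levels = c("A", "C", "G", "T")))
      first[as.character(L), ] <- as.numeric(nt) / length(uL)
    }
    list(library_id = lib,
         total_clean_reads = length(s),
         redundant_size_histogram = setNames(as.integer(red), lens),
         unique_size_histogram = setNames(as.integer(uni), lens),
         first_nt_by_length = first)
  })
  names(profiles) <- names(seqs)
  list(tags = tags, profiles = profiles)
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the collapsed-read convention `>tag<serial>_x<count>`.
#'
#' @param tags the tag data frame from [collapse_tags()].
#' @param library name of the count column to export; tags with zero count in
#'   that library are skipped.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_tag_fasta <- function(tags, library, path) {
  if (!library %in% names(tags)) invalid_arg("unknown library: ", library)
  keep <- tags[[library]] > 0
  s <- tags$sequence[keep]
  cnt <- tags[[library]][keep]
  x <- Biostrings::DNAStringSet(s)
  names(x) <- sprintf("tag%d_x%d", seq_along(s), cnt)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a per-library profile report as TSV
#'
#' @param profiles the `profiles` element from [collapse_tags()].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(library = p$library_id,
               length = as.integer(names(p$redundant_size_histogram)),
               redundant = as.integer(p$redundant_size_histogram),
               unique = as.integer(p$unique_size_histogram),
               first_A = p$first_nt_by_length[, "A"],
               first_C = p$first_nt_by_length[, "C"],
               first_G = p$first_nt_by_length[, "G"],
               first_U = p$first_nt_by_length[, "U"])
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
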