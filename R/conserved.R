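#' Default family-merge table for jointly reported miRNA families
#'
#' Some deeply conserved families are conventionally reported jointly
#' (miR156/157, miR165/166). The merge table maps a family parsed from a
#' reference name to its reported label.
#'
#' @return named character vector, `parsed family -> reported family`.
#' @export
default_family_merge <- function() {
  c(miR156 = "miR156/157", miR157 = "miR156/157",
    miR165 = "miR165/166", miR166 = "miR165/166")
}

#' Parse a miRBase-style name into its family
#'
#' Strips the species prefix (e.g. `ath-`) and the member letter/number
#' suffix, then applies the merge table: `ath-miR156a` becomes `miR156/157`.
#'
#' @param name character vector of miRBase-style names.
#' @param merge named character vector of family merges
#'   (default [default_family_merge()]).
#' @return character vector of family labels.
#' @export
mirna_family <- function(name, merge = default_family_merge()) {
  fam <- sub("^[a-zA-Z]{3,4}-", "", name)
  fam <- sub("^(miR[0-9]+).*$", "\\1", fam)
  merged <- unname(merge[fam])
  ifelse(is.na(merged), fam, merged)
}

#' Read a mature miRNA reference from FASTA
#'
#' Headers are expected to start with a miRBase-style name
#' (`spp-miR<number><suffix>`); anything after whitespace is ignored.
#' Sequences are normalized to DNA.
#'
#' @param path FASTA file of mature miRNAs.
#' @param merge family-merge table, see [mirna_family()].
#' @return a data frame with columns `name`, `family`, `sequence`.
#' @export
read_mature_reference <- function(path, merge = default_family_merge()) {
  x <- Biostrings::readDNAStringSet(path)
  name <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(name)) invalid_arg("duplicate names in mature reference")
  data.frame(name = name, family = mirna_family(name, merge),
             sequence = normalize_dna(as.character(x)), row.names = NULL)
}

#' Match a tag against a mature miRNA reference
#'
#' Equal-length, substitution-only (Hamming) matching with at most
#' `max_mismatches` differences, as in the conserved-family search. Only tags
#' of 20–22 nt are considered for the conserved search; tags outside that
#' range return no matches (they are skipped, not errors). Matches are
#' ordered best distance first, ties broken by reference name.
#'
#' @param tag a single tag sequence.
#' @param reference a reference data frame from [read_mature_reference()]
#'   (columns `name`, `family`, `sequence`).
#' @param max_mismatches maximum Hamming distance (default 2).
#' @param length_range tag lengths eligible for the search (default 20–22).
#' @return data frame with columns `tag`, `reference_name`, `family`,
#'   `mismatches`, zero rows if no match.
#' @export
match_tag <- function(tag, reference, max_mismatches = 2L,
                      length_range = c(20L, 22L)) {
  if (!is.data.frame(reference) || nrow(reference) == 0L)
    invalid_arg("empty reference")
  tag <- normalize_dna(tag)
  empty <- data.frame(tag = character(), reference_name = character(),
                      family = character(), mismatches = integer())
  L <- nchar(tag)
  if (L < length_range[1] || L > length_range[2]) return(empty)
  cand <- reference[nchar(reference$sequence) == L, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  mm <- vapply(cand$sequence, hamming, integer(1), a = tag, USE.NAMES = FALSE)
  keep <- mm <= max_mismatches
  if (!any(keep)) return(empty)
  out <- data.frame(tag = tag, reference_name = cand$name[keep],
                    family = cand$family[keep], mismatches = mm[keep])
  out[order(out$mismatches, out$reference_name), , drop = FALSE]
}

#' Reads-per-million normalization
#'
#' `matched / total * 1e6`, where `total` is the library's 18–25 nt clean
#' read total.
#'
#' @param matched_read_count reads matching the family (0 <= matched <= total).
#' @param total_clean_reads total 18–25 nt clean reads in the library (> 0).
#' @return reads per million.
#' @examples
#' compute_rpm(250, 2e6)  # 125
#' @export
compute_rpm <- function(matched_read_count, total_clean_reads) {
  if (any(total_clean_reads <= 0)) invalid_arg("total_clean_reads must be > 0")
  if (any(matched_read_count < 0 | matched_read_count > total_clean_reads))
    invalid_arg("need 0 <= matched <= total")
  matched_read_count / total_clean_reads * 1e6
}

#' Family abundance in reads per million, per library
#'
#' Assigns every eligible tag to families via [match_tag()] and sums the
#' redundant read counts per family and library; a tag matching several
#' families counts once per family. The RPM denominator is always the
#' library's full 18–25 nt clean total, not the 20–22 nt subset searched.
#'
#' @param tags tag data frame from [collapse_tags()] (`sequence` + one count
#'   column per library).
#' @param reference mature reference data frame.
#' @param totals named numeric vector of 18–25 nt clean totals per library;
#'   defaults to the column sums of `tags`.
#' @param max_mismatches maximum Hamming distance (default 2).
#' @return data frame with `family` and one RPM column per library.
#' @export
family_abundance <- function(tags, reference, totals = NULL,
                             max_mismatches = 2L) {
  libs <- setdiff(names(tags), "sequence")
  if (is.null(totals)) totals <- vapply(tags[libs], sum, numeric(1))
  hits <- lapply(tags$sequence, match_tag, reference = reference,
                 max_mismatches = max_mismatches)
  fam_of_tag <- lapply(hits, function(h) unique(h$family))
  families <- sort(unique(unlist(fam_of_tag)))
  out <- data.frame(family = families)
  for (lib in libs) {
    counts <- setNames(numeric(length(families)), families)
    for (k in seq_along(fam_of_tag)) {
      for (f in fam_of_tag[[k]]) counts[f] <- counts[f] + tags[[lib]][k]
    }
    out[[lib]] <- compute_rpm(unname(counts), totals[[lib]])
  }
  out
}
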