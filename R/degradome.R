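#' Build a t-plot profile for one transcript
#'
#' Sums degradome 5'-end tag counts by transcript position. Positions
#' without tags are 0; the profile sums to the total tag count.
#'
#' @param tags data frame of degradome tags for a single transcript, with
#'   columns `five_prime_position` (0-based transcript coordinate of the tag
#'   5' end) and `count` (>= 1); zero rows allowed.
#' @param transcript_length length of the transcript.
#' @return numeric vector of length `transcript_length`; element `p + 1` is
#'   the count at 0-based position `p`.
#' @export
build_tplot <- function(tags, transcript_length) {
  profile <- numeric(transcript_length)
  if (nrow(tags) > 0) {
    if (any(tags$five_prime_position < 0 |
            tags$five_prime_position >= transcript_length))
      invalid_arg("tag position outside transcript")
    for (k in seq_len(nrow(tags))) {
      p <- tags$five_prime_position[k] + 1L
      profile[p] <- profile[p] + tags$count[k]
    }
  }
  profile
}

#' Categorize a degradome position on its t-plot
#'
#' Categories follow the CleaveLand lineage:
#' \describe{
#'   \item{0}{count > 1 and the unique maximum of the profile,}
#'   \item{1}{count > 1 and equal to a shared (tied) maximum,}
#'   \item{2}{count > 1, below the maximum, above the median of the nonzero
#'     counts,}
#'   \item{3}{count > 1, at or below that median,}
#'   \item{4}{count exactly 1 (a singleton read).}
#' }
#' The rules are mutually exclusive and exhaustive for any position with a
#' nonzero count; categories 0–1 are invariant under uniform scaling of all
#' counts.
#'
#' @param profile t-plot profile from [build_tplot()].
#' @param position 0-based transcript position; its count must be nonzero.
#' @return integer category 0–4.
#' @export
categorize_peak <- function(profile, position) {
  if (length(profile) == 0) invalid_arg("empty profile")
  count <- profile[position + 1L]
  if (is.na(count) || count == 0) invalid_arg("position with zero count")
  if (count == 1) return(4L)
  mx <- max(profile)
  if (count == mx)
    return(if (sum(profile == mx) == 1L) 0L else 1L)
  med <- median(profile[profile > 0])
  if (count > med) 2L else 3L
}

#' Confirm miRNA-guided cleavage sites from degradome t-plots
#'
#' A predicted target site is confirmed when a t-plot peak of category at
#' most 2 lies within `window` nt of the position opposite miRNA positions
#' 10–11: cleavage falls between the target bases paired to miRNA positions
#' 10 and 11, and the degradome tag marks the 5' end of the 3' fragment,
#' i.e. the base paired to miRNA position 10. For a site spanning
#' `start..end` (1-based) that base is `end - 9` (0-based: `end - 10`).
#'
#' @param sites target-site data frame from [scan_targets()].
#' @param tplots named list of t-plot profiles (one per transcript,
#'   from [build_tplot()]).
#' @param window peak search window in nt around the expected slice position
#'   (default 1).
#' @return data frame with one row per site: `mirna_name`, `transcript_id`,
#'   `site_start`, `site_end`, `expectation`, `cleavage_position` (0-based),
#'   `peak_position`, `peak_count`, `category` (all `NA` when no qualifying
#'   peak), `confirmed`, and `status` (`"confirmed"`, `"no peak"` or
#'   `"no data"`).
#' @export
confirm_cleavage <- function(sites, tplots, window = 1L) {
  rows <- lapply(seq_len(nrow(sites)), function(k) {
    s <- sites[k, ]
    cpos <- s$end - 10L   # 0-based position paired to miRNA position 10
    out <- data.frame(mirna_name = s$mirna_name,
                      transcript_id = s$transcript_id,
                      site_start = s$start, site_end = s$end,
                      expectation = s$expectation,
                      cleavage_position = cpos,
                      peak_position = NA_integer_, peak_count = NA_real_,
                      category = NA_integer_, confirmed = FALSE,
                      status = "no data")
    profile <- tplots[[s$transcript_id]]
    if (is.null(profile)) return(out)
    out$status <- "no peak"
    cand <- (cpos - window):(cpos + window)
    cand <- cand[cand >= 0 & cand < length(profile)]
    cand <- cand[profile[cand + 1L] > 0]
    if (length(cand) == 0) return(out)
    cats <- vapply(cand, categorize_peak, integer(1), profile = profile)
    ok <- cats <= 2L
    if (!any(ok)) return(out)
    best <- cand[ok][order(cats[ok], -profile[cand[ok] + 1L])][1]
    out$peak_position <- best
    out$peak_count <- profile[best + 1L]
    out$category <- cats[ok][order(cats[ok], -profile[cand[ok] + 1L])][1]
    out$confirmed <- TRUE
    out$status <- "confirmed"
    out
  })
  if (length(rows) == 0)
    return(data.frame(mirna_name = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      expectation = numeric(), cleavage_position = integer(),
                      peak_position = integer(), peak_count = numeric(),
                      category = integer(), confirmed = logical(),
                      status = character()))
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Read degradome 5'-end tags from FASTA and map them onto transcripts
#'
#' Tags are placed by exact matching of the tag sequence to the transcript
#' (sense strand): the 5' end of the tag marks the 5' end of an uncapped
#' 3' cleavage fragment.
#'
#' @param path FASTA of degradome tags.
#' @param transcripts named character vector or `DNAStringSet`.
#' @return data frame with `sequence`, `transcript_id`,
#'   `five_prime_position` (0-based) and `count` (collapsed duplicates).
#' @export
read_degradome_tags <- function(path, transcripts) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- normalize_dna(as.character(x))
  tab <- table(seqs)
  if (!methods::is(transcripts, "DNAStringSet"))
    transcripts <- Biostrings::DNAStringSet(normalize_dna(transcripts))
  rows <- list()
  for (s in names(tab)) {
    hits <- Biostrings::vmatchPattern(s, transcripts)
    for (ci in seq_along(hits)) {
      st <- BiocGenerics::start(hits[[ci]])
      if (length(st) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = s, transcript_id = names(transcripts)[ci],
        five_prime_position = st - 1L, count = as.integer(tab[[s]]))
    }
  }
  if (length(rows) == 0)
    return(data.frame(sequence = character(), transcript_id = character(),
                      five_prime_position = integer(), count = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$five_prime_position, out$sequence), ]
  row.names(out) <- NULL
  out
}
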