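## pairing class of a miRNA base against a target base (both DNA alphabet,
## target read 3'->5' so the two characters face each other)
.pair_class <- function(mb, tb) {
  wc <- (mb == "A" & tb == "T") | (mb == "T" & tb == "A") |
    (mb == "C" & tb == "G") | (mb == "G" & tb == "C")
  wob <- (mb == "G" & tb == "T") | (mb == "T" & tb == "G")
  ifelse(mb == "-" | tb == "-", "gap",
         ifelse(wc, "match", ifelse(wob, "wobble", "mismatch")))
}

#' Score a miRNA/target-site alignment with the expectation scheme
#'
#' The expectation is the penalty sum over alignment columns, read from the
#' miRNA 5' end: match 0, G:U wobble 0.5, mismatch 1.0, each gap 2.0, with
#' penalties multiplied by 1.5 at miRNA positions 2–13 (the seed region).
#' Lower is better; a perfect complement scores 0.
#'
#' For the common ungapped case pass the miRNA and the target site both
#' written 5' to 3'; the site is reversed internally so columns face each
#' other antiparallel. A gapped alignment is supplied explicitly via
#' `alignment`: two equal-length strings with `-`, the miRNA 5' to 3' and the
#' target site 3' to 5'.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param site target site on the transcript, 5' to 3' (ungapped case; must
#'   equal the miRNA length).
#' @param alignment optional list with elements `mirna` and `target`
#'   (aligned strings; target 3' to 5').
#' @param seed_range miRNA positions with the seed multiplier (default 2–13).
#' @param penalties named vector of penalties
#'   (default `c(match = 0, wobble = 0.5, mismatch = 1, gap = 2)`).
#' @param seed_multiplier penalty multiplier inside the seed (default 1.5).
#' @return a list (`duplex_score`) with `expectation`, `classes` (per-column
#'   pairing class) and `mirna_position` (miRNA position of each column,
#'   `NA` at miRNA gaps).
#' @examples
#' score_duplex("TGACAGAAGA", revcomp("TGACAGAAGA"))$expectation  # 0
#' @export
score_duplex <- function(mirna, site = NULL, alignment = NULL,
                         seed_range = c(2L, 13L),
                         penalties = c(match = 0, wobble = 0.5,
                                       mismatch = 1, gap = 2),
                         seed_multiplier = 1.5) {
  if (is.null(alignment)) {
    mirna <- normalize_dna(mirna)
    site <- normalize_dna(site)
    if (nchar(mirna) != nchar(site))
      invalid_arg("length mismatch without gap annotation")
    m <- strsplit(mirna, "")[[1]]
    t <- rev(strsplit(site, "")[[1]])
  } else {
    m <- strsplit(toupper(alignment$mirna), "")[[1]]
    t <- strsplit(toupper(alignment$target), "")[[1]]
    m[m == "U"] <- "T"; t[t == "U"] <- "T"
    if (length(m) != length(t))
      invalid_arg("aligned strings must have equal length")
  }
  cls <- .pair_class(m, t)
  mpos <- cumsum(m != "-")
  posw <- pmax(mpos, 1L)      # miRNA-gap columns weighted by the last
                              # miRNA position passed
  mpos[m == "-"] <- NA
  seed <- posw >= seed_range[1] & posw <= seed_range[2]
  pen <- unname(penalties[cls]) * ifelse(seed, seed_multiplier, 1)
  structure(list(expectation = sum(pen), classes = cls,
                 mirna_position = mpos),
            class = "duplex_score")
}

#' Classify the inhibition mode of a scored target site
#'
#' Cleavage requires pairing across the slicing centre: the site is
#' classified as `translation` if and only if an unpaired column (mismatch or
#' gap) covers miRNA position 10 or 11; `cleavage` otherwise. G:U wobbles
#' count as paired.
#'
#' @param score a `duplex_score` from [score_duplex()].
#' @return `"cleavage"` or `"translation"`.
#' @export
classify_inhibition <- function(score) {
  central <- !is.na(score$mirna_position) & score$mirna_position %in% c(10L, 11L)
  unpaired <- score$classes %in% c("mismatch", "gap")
  if (any(central & unpaired)) "translation" else "cleavage"
}

#' Scan transcripts for miRNA target sites
#'
#' Slides the miRNA over every transcript position (ungapped, antiparallel)
#' and reports every site with expectation at most `max_expectation`,
#' best-first. The site region is labelled from an optional ORF interval
#' table, otherwise `"unknown"`. Gapped sites are only reachable through a
#' manual alignment passed to [score_duplex()]; such curated pairs can be
#' appended to the report with `manual = TRUE`.
#'
#' @param mirna miRNA sequence (5' to 3').
#' @param transcripts named character vector or `DNAStringSet`.
#' @param max_expectation report threshold (default 3.0).
#' @param orf optional data frame with `transcript_id`, `orf_start`,
#'   `orf_end` (1-based inclusive coordinates of the coding region).
#' @param mirna_name name used in the report (default `"mirna"`).
#' @return data frame with `mirna_name`, `transcript_id`, `start`, `end`
#'   (1-based site span), `expectation`, `region`
#'   (`5' UTR` / `ORF` / `3' UTR` / `unknown`), `inhibition`, `manual`;
#'   ordered by increasing expectation.
#' @export
scan_targets <- function(mirna, transcripts, max_expectation = 3,
                         orf = NULL, mirna_name = "mirna") {
  if (methods::is(transcripts, "DNAStringSet"))
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  if (length(transcripts) == 0)
    return(data.frame(mirna_name = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), region = character(),
                      inhibition = character(), manual = logical()))
  if (is.null(names(transcripts))) invalid_arg("transcripts must be named")
  mirna <- normalize_dna(mirna)
  L <- nchar(mirna)
  rows <- list()
  for (tx in names(transcripts)) {
    s <- normalize_dna(transcripts[[tx]])
    n <- nchar(s)
    if (n < L) next
    for (st in seq_len(n - L + 1L)) {
      site <- substr(s, st, st + L - 1L)
      sc <- score_duplex(mirna, site)
      if (sc$expectation > max_expectation) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_name = mirna_name, transcript_id = tx, start = st,
        end = st + L - 1L, expectation = sc$expectation,
        region = .site_region(tx, st, st + L - 1L, orf),
        inhibition = classify_inhibition(sc), manual = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(mirna_name = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), region = character(),
                      inhibition = character(), manual = logical()))
  out <- do.call(rbind, rows)
  out <- out[order(out$expectation, out$transcript_id, out$start), ]
  row.names(out) <- NULL
  out
}

.site_region <- function(tx, start, end, orf) {
  if (is.null(orf)) return("unknown")
  row <- orf[orf$transcript_id == tx, , drop = FALSE]
  if (nrow(row) == 0) return("unknown")
  if (end < row$orf_start[1]) return("5' UTR")
  if (start > row$orf_end[1]) return("3' UTR")
  "ORF"
}
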