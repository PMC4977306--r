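#' Anchor tags on transcriptome contigs by perfect matching
#'
#' Reports every exact occurrence of each tag on either strand of the contig
#' set (minus-strand occurrences are found via the reverse complement and
#' reported with forward-strand coordinates).
#'
#' @param tags character vector of tag sequences.
#' @param contigs a named character vector or `DNAStringSet` of contigs.
#' @return data frame with columns `tag`, `contig_id`, `position` (0-based
#'   start of the occurrence on the forward strand) and `strand` (`+`/`-`).
#' @export
anchor_tags <- function(tags, contigs) {
  if (!methods::is(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(normalize_dna(contigs))
  if (is.null(names(contigs))) invalid_arg("contigs must be named")
  out <- list()
  for (tag in unique(normalize_dna(tags))) {
    for (strand in c("+", "-")) {
      probe <- if (strand == "+") tag else revcomp(tag)
      hits <- Biostrings::vmatchPattern(probe, contigs)
      for (ci in seq_along(hits)) {
        st <- BiocGenerics::start(hits[[ci]])
        if (length(st) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          tag = tag, contig_id = names(contigs)[ci],
          position = st - 1L, strand = strand)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(tag = character(), contig_id = character(),
                      position = integer(), strand = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$tag, res$contig_id, res$position, res$strand), ]
  row.names(res) <- NULL
  res
}

#' Extract a candidate precursor window around an anchored tag
#'
#' The window extends up to `flank` nt upstream and downstream of the tag,
#' clipped at the contig ends: `[max(0, pos - flank), min(len, pos + tag_len
#' + flank))` in 0-based half-open forward-strand coordinates. For
#' minus-strand anchors the returned sequence is the reverse complement of
#' the forward slice; the recorded coordinates stay on the forward strand.
#'
#' @param contig_seq the contig sequence (single string).
#' @param position 0-based forward-strand start of the tag occurrence.
#' @param tag_len tag length.
#' @param strand `"+"` or `"-"`.
#' @param flank flank size in nt (default 200).
#' @return a list (`precursor_window`) with `start`, `end`, `strand`,
#'   `sequence`, and `tag_start`: the 0-based offset of the tag inside
#'   `sequence` (already strand-corrected).
#' @export
extract_window <- function(contig_seq, position, tag_len, strand = "+",
                           flank = 200L) {
  contig_seq <- normalize_dna(contig_seq)
  len <- nchar(contig_seq)
  if (position < 0 || position + tag_len > len)
    invalid_arg("anchor outside contig")
  start <- max(0L, position - flank)
  end <- min(len, position + tag_len + flank)
  fwd <- substr(contig_seq, start + 1L, end)
  if (strand == "+") {
    seq <- fwd
    tag_start <- position - start
  } else {
    seq <- revcomp(fwd)
    tag_start <- end - (position + tag_len)
  }
  structure(list(start = start, end = end, strand = strand, sequence = seq,
                 tag_start = as.integer(tag_start)),
            class = "precursor_window")
}

## Estimated pairing partner of position x, extrapolating antiparallel from
## the nearest paired position inside span [lo, hi]; NA if no position in the
## span is paired.
.partner_near <- function(partner, x, lo, hi) {
  paired <- which(!is.na(partner[lo:hi])) + lo - 1L
  if (length(paired) == 0) return(NA_integer_)
  if (!is.na(partner[x])) return(partner[x])
  xp <- paired[which.min(abs(paired - x))]
  as.integer(partner[xp] - (x - xp))
}

#' Locate the miRNA/miRNA* duplex on a folded precursor
#'
#' The star arm is inferred by the Dicer 2-nt 3'-overhang rule applied to the
#' pairing partners of the miRNA span: the star runs from the partner of
#' miRNA position `L - 2` to the partner of miRNA position 1 plus 2 (both in
#' precursor coordinates; the rule is symmetric for 5'- and 3'-arm miRNAs).
#' If the boundary positions are unpaired, the partner is extrapolated from
#' the nearest paired position; the overhang criterion is then recorded as
#' failed because the duplex ends are not cleanly base-paired.
#'
#' @param struct a `hairpin_structure` from [fold_rna()].
#' @param mir_start 1-based start of the miRNA on the precursor.
#' @param mir_len miRNA length.
#' @return a list (`duplex_report`) with `mirna_span`, `star_span` (1-based
#'   inclusive, or `NULL` if no stem), `mismatches` (unpaired miRNA duplex
#'   positions), `asymmetric_bulges` (data frame of size/side),
#'   `overhang_3prime` (logical: clean 2-nt 3' overhang geometry), and
#'   `has_stem`.
#' @export
locate_duplex <- function(struct, mir_start, mir_len) {
  n <- nchar(struct$sequence)
  m1 <- as.integer(mir_start)
  m2 <- m1 + as.integer(mir_len) - 1L
  if (m1 < 1 || m2 > n) invalid_arg("miRNA span outside precursor")
  partner <- struct$partner
  no_stem <- list(mirna_span = c(m1, m2), star_span = NULL,
                  mismatches = NA_integer_,
                  asymmetric_bulges = data.frame(size = integer(),
                                                 side = character()),
                  overhang_3prime = FALSE, has_stem = FALSE)
  class(no_stem) <- "duplex_report"
  dup_hi <- m2 - 2L                 # duplex region excludes the 2-nt 3' overhang
  if (dup_hi < m1) return(no_stem)
  s_a <- .partner_near(partner, dup_hi, m1, dup_hi)
  s_b <- .partner_near(partner, m1, m1, dup_hi)
  if (is.na(s_a) || is.na(s_b)) return(no_stem)
  star <- sort(c(s_a, s_b + 2L))
  star[1] <- max(1L, star[1]); star[2] <- min(n, star[2])
  if (star[1] > star[2] || (star[1] <= m2 && star[2] >= m1))
    return(no_stem)                 # spans overlap: not a two-arm stem
  in_star <- function(p) !is.na(p) & p >= star[1] & p <= star[2]
  dup_pos <- m1:dup_hi
  paired_ok <- in_star(partner[dup_pos])
  mism <- sum(!paired_ok)
  # walk consecutive duplex-paired positions for asymmetric bulges
  bp <- dup_pos[paired_ok]
  sizes <- integer(); sides <- character()
  if (length(bp) >= 2) {
    for (t in seq_len(length(bp) - 1L)) {
      gm <- bp[t + 1L] - bp[t] - 1L
      gs <- abs(partner[bp[t]] - partner[bp[t + 1L]]) - 1L
      if (gm != gs) {
        sizes <- c(sizes, abs(gm - gs))
        sides <- c(sides, if (gm > gs) "mirna" else "star")
      }
    }
  }
  overhang <- !is.na(partner[dup_hi]) && !is.na(partner[m1]) &&
    partner[dup_hi] %in% star[1]:star[2] && partner[m1] %in% star[1]:star[2]
  structure(list(mirna_span = c(m1, m2), star_span = star,
                 mismatches = as.integer(mism),
                 asymmetric_bulges = data.frame(size = sizes, side = sides),
                 overhang_3prime = overhang, has_stem = TRUE),
            class = "duplex_report")
}

#' Apply the five hairpin validity criteria to a folded candidate
#'
#' A candidate is a valid miRNA precursor if
#' (1) the hairpin MFE is at most `mfe_max` (default -35 kcal/mol);
#' (2) the miRNA/miRNA* duplex has at most `max_mismatches` mismatches
#'     (default 4; G:U wobbles count as pairs, not mismatches);
#' (3) the stem has at most `max_asym_bulges` asymmetric bulge (default 1)
#'     of size at most `max_bulge_size` nt (default 2);
#' (4) the miRNA : miRNA* read ratio is at least `min_ratio` (default 5);
#' (5) the duplex shows clean 2-nt 3' overhangs on both arms.
#'
#' The verdicts are computed independently; `valid` is their conjunction.
#' When no star reads are observed, criterion (4) is recorded as `NA`
#' ("not evaluable") and the candidate is reported but not valid, mirroring
#' the retention-with-flag treatment of precursors whose star strand was
#' never sequenced. A structure without any stem fails all duplex criteria
#' (this is not an error).
#'
#' @param struct a `hairpin_structure` from [fold_rna()].
#' @param mir_start,mir_len 1-based miRNA start and length on the precursor.
#' @param mirna_reads,star_reads read counts supporting the miRNA and star
#'   sequences.
#' @param mfe_max,max_mismatches,max_asym_bulges,max_bulge_size,min_ratio
#'   thresholds as above.
#' @return a list with `criteria` (named logical vector `mfe`, `duplex_mismatches`,
#'   `asymmetric_bulge`, `read_ratio` (possibly `NA`), `overhang`), `valid`,
#'   `read_ratio` (may be `Inf`), `star_evaluable`, and the `duplex` report.
#' @export
evaluate_criteria <- function(struct, mir_start, mir_len, mirna_reads,
                              star_reads, mfe_max = -35,
                              max_mismatches = 4L, max_asym_bulges = 1L,
                              max_bulge_size = 2L, min_ratio = 5) {
  duplex <- locate_duplex(struct, mir_start, mir_len)
  c1 <- struct$mfe <= mfe_max
  if (!duplex$has_stem) {
    c2 <- FALSE; c3 <- FALSE; c5 <- FALSE
  } else {
    c2 <- duplex$mismatches <= max_mismatches
    nb <- nrow(duplex$asymmetric_bulges)
    c3 <- nb <= max_asym_bulges &&
      (nb == 0 || all(duplex$asymmetric_bulges$size <= max_bulge_size))
    c5 <- duplex$overhang_3prime
  }
  star_evaluable <- star_reads > 0
  ratio <- if (star_reads > 0) mirna_reads / star_reads else Inf
  c4 <- if (star_evaluable) ratio >= min_ratio else NA
  criteria <- c(mfe = c1, duplex_mismatches = c2, asymmetric_bulge = c3,
                read_ratio = c4, overhang = c5)
  list(criteria = criteria,
       valid = all(vapply(criteria, isTRUE, logical(1))),
       read_ratio = ratio, star_evaluable = star_evaluable, duplex = duplex)
}

#' Thermodynamic statistics of a precursor
#'
#' AMFE is the MFE per 100 nt of hairpin; GC% is computed from the precursor
#' sequence (or supplied directly); MFEI is the magnitude of AMFE divided by
#' GC%. Values are kept at full precision; rounding to 2 decimals happens
#' only in report writers.
#'
#' @param sequence precursor sequence; may be `NULL` if `hairpin_length` and
#'   `gc_percent` are both supplied.
#' @param mfe minimum free energy, kcal/mol (<= 0).
#' @param hairpin_length hairpin length in nt; defaults to `nchar(sequence)`.
#' @param gc_percent GC percentage 0–100; computed from `sequence` if absent.
#' @param amfe adjusted MFE; computed as `mfe / hairpin_length * 100` if absent.
#' @return a list (`thermo_stats`) with `mfe`, `hairpin_length`, `amfe`,
#'   `gc_percent`, `mfei` and `mfei_defined` (`FALSE` and `mfei = NA` when
#'   GC% is zero).
#' @examples
#' thermo_stats(mfe = -92, hairpin_length = 258, gc_percent = 39.53)$amfe
#' @export
thermo_stats <- function(sequence = NULL, mfe, hairpin_length = NULL,
                         gc_percent = NULL, amfe = NULL) {
  if (mfe > 0) invalid_arg("mfe must be <= 0")
  if (!is.null(sequence)) {
    sequence <- normalize_dna(sequence)
    if (nchar(sequence) == 0) invalid_arg("empty sequence")
    if (is.null(hairpin_length)) hairpin_length <- nchar(sequence)
    if (is.null(gc_percent)) {
      bases <- strsplit(sequence, "")[[1]]
      gc_percent <- sum(bases %in% c("G", "C")) / length(bases) * 100
    }
  }
  if (is.null(hairpin_length) || is.null(gc_percent))
    invalid_arg("need a sequence, or hairpin_length and gc_percent")
  if (is.null(amfe)) amfe <- mfe / hairpin_length * 100
  mfei_defined <- gc_percent > 0
  mfei <- if (mfei_defined) abs(amfe) / gc_percent else NA_real_
  structure(list(mfe = mfe, hairpin_length = hairpin_length, amfe = amfe,
                 gc_percent = gc_percent, mfei = mfei,
                 mfei_defined = mfei_defined),
            class = "thermo_stats")
}

#' Discover candidate miRNA precursors on a transcriptome
#'
#' Runs the discovery stage end-to-end: anchors each eligible tag on the
#' contigs by perfect matching, extracts the flanked precursor window, folds
#' it, locates the miRNA/miRNA* duplex, applies the five validity criteria
#' and computes the thermodynamic statistics and per-library RPM.
#'
#' Star read support is looked up as the summed counts of any tag whose
#' sequence equals the inferred star sequence. Windows shorter than
#' `min_window` or longer than `max_window` nt are rejected (not errors).
#'
#' @param tags tag data frame from [collapse_tags()] (`sequence` plus one
#'   count column per library).
#' @param contigs named character vector or `DNAStringSet` of contigs.
#' @param totals named vector of 18–25 nt clean totals per library for the
#'   RPM denominator; defaults to column sums of `tags`.
#' @param flank precursor window flank (default 200 nt).
#' @param tag_length_range tag lengths considered for discovery
#'   (default 20–24 nt).
#' @param min_window,max_window window length limits for folding
#'   (defaults 30 and 500).
#' @param mfe_max,max_mismatches,max_asym_bulges,max_bulge_size,min_ratio
#'   criteria thresholds, see [evaluate_criteria()].
#' @return a data frame of candidates, one row per anchored window: tag,
#'   contig coordinates, strand, per-library RPM (`rpm_<library>`), precursor
#'   sequence and dot-bracket, hairpin length, MFE, AMFE, GC%, MFEI, star
#'   sequence (`NA` if no stem), read ratio, the five criterion verdicts
#'   (`crit_mfe` ... `crit_overhang`), `star_evaluable` and `valid`.
#' @export
discover_precursors <- function(tags, contigs, totals = NULL, flank = 200L,
                                tag_length_range = c(20L, 24L),
                                min_window = 30L, max_window = 500L,
                                mfe_max = -35, max_mismatches = 4L,
                                max_asym_bulges = 1L, max_bulge_size = 2L,
                                min_ratio = 5) {
  if (!methods::is(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(normalize_dna(contigs))
  libs <- setdiff(names(tags), "sequence")
  if (is.null(totals)) totals <- vapply(tags[libs], sum, numeric(1))
  lens <- nchar(tags$sequence)
  eligible <- tags$sequence[lens >= tag_length_range[1] &
                              lens <= tag_length_range[2]]
  anchors <- anchor_tags(eligible, contigs)
  rows <- list()
  for (k in seq_len(nrow(anchors))) {
    a <- anchors[k, ]
    tag_len <- nchar(a$tag)
    win <- extract_window(as.character(contigs[[a$contig_id]]), a$position,
                          tag_len, a$strand, flank)
    wlen <- nchar(win$sequence)
    if (wlen < min_window || wlen > max_window) next
    struct <- fold_rna(win$sequence)
    ti <- match(a$tag, tags$sequence)
    mirna_reads <- sum(vapply(libs, function(l) tags[[l]][ti], numeric(1)))
    ev0 <- locate_duplex(struct, win$tag_start + 1L, tag_len)
    star_seq <- NA_character_
    star_reads <- 0
    if (ev0$has_stem) {
      star_seq <- substr(struct$sequence, ev0$star_span[1], ev0$star_span[2])
      si <- match(star_seq, tags$sequence)
      if (!is.na(si))
        star_reads <- sum(vapply(libs, function(l) tags[[l]][si], numeric(1)))
    }
    ev <- evaluate_criteria(struct, win$tag_start + 1L, tag_len, mirna_reads,
                            star_reads, mfe_max, max_mismatches,
                            max_asym_bulges, max_bulge_size, min_ratio)
    ts <- thermo_stats(struct$sequence, struct$mfe)
    row <- data.frame(
      tag = a$tag, contig_id = a$contig_id, start = win$start,
      end = win$end, strand = a$strand, length = tag_len,
      hairpin_length = wlen, mfe = struct$mfe, amfe = ts$amfe,
      gc_percent = ts$gc_percent, mfei = ts$mfei,
      precursor = struct$sequence, dot_bracket = struct$dot_bracket,
      star_sequence = star_seq, read_ratio = ev$read_ratio,
      star_evaluable = ev$star_evaluable)
    for (l in libs) row[[paste0("rpm_", l)]] <- compute_rpm(tags[[l]][ti],
                                                            totals[[l]])
    cr <- ev$criteria
    row$crit_mfe <- cr[["mfe"]]
    row$crit_duplex_mismatches <- cr[["duplex_mismatches"]]
    row$crit_asymmetric_bulge <- cr[["asymmetric_bulge"]]
    row$crit_read_ratio <- cr[["read_ratio"]]
    row$crit_overhang <- cr[["overhang"]]
    row$valid <- ev$valid
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0) return(data.frame())
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Write a candidate precursor report as TSV
#'
#' Columns follow the conserved/novel precursor table layout (name, mature
#' sequence printed as RNA, strand, per-library RPM, mature and hairpin
#' length, MFE, AMFE, GC%, MFEI rounded to 2 decimals, star sequence).
#'
#' @param candidates data frame from [discover_precursors()].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_candidate_tsv <- function(candidates, path) {
  rpm_cols <- grep("^rpm_", names(candidates), value = TRUE)
  out <- data.frame(name = sprintf("cand-%03d", seq_len(nrow(candidates))),
                    sequence = as_rna(candidates$tag),
                    strand = candidates$strand)
  for (cc in rpm_cols) out[[cc]] <- round(candidates[[cc]], 1)
  out$length <- candidates$length
  out$hairpin_length <- candidates$hairpin_length
  out$mfe <- round(candidates$mfe, 2)
  out$amfe <- round(candidates$amfe, 2)
  out$gc_percent <- round(candidates$gc_percent, 2)
  out$mfei <- round(candidates$mfei, 2)
  out$star_sequence <- ifelse(is.na(candidates$star_sequence), "ND",
                              as_rna(candidates$star_sequence))
  out$valid <- candidates$valid
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
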