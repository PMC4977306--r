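# builds a contig with a perfect hairpin (arm + loop + revcomp(arm)) between
# unstructured A/C flanks; returns coordinates of the planted miRNA
planted_hairpin <- function(arm_len = 60, loop = "AACCACAA", offset = 20,
                            mir_len = 21, flank = 120) {
  arm <- random_rna(arm_len)
  hp <- paste0(arm, loop, revcomp(arm))
  contig <- paste0(paste(sample(c("A", "C"), flank, TRUE), collapse = ""), hp,
                   paste(sample(c("A", "C"), flank, TRUE), collapse = ""))
  list(contig = contig, hairpin = hp, arm = arm,
       mir = substr(arm, offset + 1, offset + mir_len),
       mir_pos = flank + offset,   # 0-based on contig
       hp_start = flank, offset = offset, mir_len = mir_len)
}

naive_anchor_scan <- function(tag, contigs) {
  hits <- list()
  for (cid in names(contigs)) {
    s <- contigs[[cid]]
    for (probe_strand in list(c(tag, "+"), c(revcomp(tag), "-"))) {
      p <- gregexpr(probe_strand[1], s, fixed = TRUE)[[1]]
      if (p[1] != -1)
        for (pp in p) hits[[length(hits) + 1L]] <-
          data.frame(tag = tag, contig_id = cid, position = pp - 1L,
                     strand = probe_strand[2])
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(tag = character(), contig_id = character(),
                  position = integer(), strand = character())
}

test_that("anchoring reports every exact occurrence on both strands", {
  set.seed(31)
  contigs <- c(c1 = random_rna(400), c2 = random_rna(400))
  tag_fwd <- substr(contigs[["c1"]], 101, 121)
  tag_rev <- revcomp(substr(contigs[["c2"]], 201, 221))
  absent <- random_rna(21)
  for (tag in c(tag_fwd, tag_rev, absent)) {
    got <- anchor_tags(tag, contigs)
    want <- naive_anchor_scan(tag, contigs)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      key <- function(d) sort(paste(d$contig_id, d$position, d$strand))
      expect_equal(key(got), key(want))
    }
  }
  expect_equal(anchor_tags(tag_rev, contigs)$strand, "-")
})

test_that("window extraction clips at contig ends and handles strands", {
  contig <- random_rna(1000)
  # anchor at position 0: no upstream flank
  w <- extract_window(contig, 0, 21, "+", flank = 200)
  expect_equal(w$start, 0)
  expect_equal(w$end, 221)
  expect_equal(w$tag_start, 0)
  # mid-contig: full 421-nt window
  w <- extract_window(contig, 400, 21, "+", flank = 200)
  expect_equal(w$end - w$start, 421)
  expect_equal(nchar(w$sequence), 421)
  expect_equal(substr(w$sequence, w$tag_start + 1, w$tag_start + 21),
               substr(contig, 401, 421))
  # minus strand: reverse complement of the forward slice
  w <- extract_window(contig, 400, 21, "-", flank = 200)
  expect_equal(w$sequence, revcomp(substr(contig, 201, 621)))
  expect_equal(substr(w$sequence, w$tag_start + 1, w$tag_start + 21),
               revcomp(substr(contig, 401, 421)))
  expect_error(extract_window(contig, 990, 21), "outside")
})

test_that("duplex location applies the 2-nt 3'-overhang rule symmetrically", {
  set.seed(32)
  ph <- planted_hairpin()
  s <- fold_rna(ph$hairpin)
  d <- locate_duplex(s, ph$offset + 1, ph$mir_len)
  expect_true(d$has_stem)
  expect_equal(d$mismatches, 0L)
  A <- nchar(ph$arm); l <- 8; a <- ph$offset
  expect_equal(d$star_span, c(2 * A + l - a - ph$mir_len + 2 + 1,
                              2 * A + l - a + 2))
  # star of the star is the original miRNA span (the rule is an involution)
  d2 <- locate_duplex(s, d$star_span[1], ph$mir_len)
  expect_equal(d2$star_span, c(ph$offset + 1, ph$offset + ph$mir_len))
  # no stem: unstructured sequence
  flatseq <- paste(rep(c("A", "C"), 30), collapse = "")
  d3 <- locate_duplex(fold_rna(flatseq), 5, 21)
  expect_false(d3$has_stem)
})

test_that("the five criteria pass on a clean duplex and fail one by one", {
  set.seed(33)
  ph <- planted_hairpin()
  s <- fold_rna(ph$hairpin)
  m1 <- ph$offset + 1
  ev <- evaluate_criteria(s, m1, ph$mir_len, mirna_reads = 100, star_reads = 10)
  expect_true(ev$valid)
  expect_true(all(ev$criteria))

  # (1) weak hairpin: MFE above -35
  weak <- fold_rna("GGGGGAAAACCCCC")
  evw <- evaluate_criteria(weak, 1, 5, 100, 10)
  expect_false(evw$criteria[["mfe"]])
  expect_false(evw$valid)

  # (2) five duplex mismatches: mutate five star-side bases facing the miRNA
  arm <- ph$arm
  hp2 <- ph$hairpin
  n <- nchar(hp2)
  mut_targets <- vapply(m1 + c(3, 5, 7, 9, 11) - 1, function(x) n + 1 - x,
                        numeric(1))
  for (x in mut_targets) {
    old <- substr(hp2, x, x)
    substr(hp2, x, x) <- setdiff(c("A", "C", "G", "T"),
                                 c(old, chartr("ACGT", "TGCA", old)))[1]
  }
  s2 <- fold_rna(hp2)
  ev2 <- evaluate_criteria(s2, m1, ph$mir_len, 100, 10)
  expect_false(ev2$criteria[["duplex_mismatches"]])

  # (4) read ratio 4:1 fails the 5:1 requirement
  ev4 <- evaluate_criteria(s, m1, ph$mir_len, mirna_reads = 40, star_reads = 10)
  expect_false(ev4$criteria[["read_ratio"]])
  expect_false(ev4$valid)

  # star never sequenced: criterion 4 not evaluable, candidate flagged
  ev0 <- evaluate_criteria(s, m1, ph$mir_len, mirna_reads = 40, star_reads = 0)
  expect_true(is.na(ev0$criteria[["read_ratio"]]))
  expect_false(ev0$star_evaluable)
  expect_false(ev0$valid)
})

test_that("criteria verdicts are monotone in mismatches and star counts", {
  set.seed(34)
  ph <- planted_hairpin()
  m1 <- ph$offset + 1
  n <- nchar(ph$hairpin)
  # progressively mutate star-side bases facing the miRNA
  hp <- ph$hairpin
  fails <- FALSE
  for (k in seq(3, 13, by = 2)) {
    x <- n + 1 - (m1 + k - 1)
    old <- substr(hp, x, x)
    substr(hp, x, x) <- setdiff(c("A", "C", "G", "T"),
                                c(old, chartr("ACGT", "TGCA", old)))[1]
    ev <- evaluate_criteria(fold_rna(hp), m1, ph$mir_len, 100, 10)
    if (fails) expect_false(isTRUE(ev$criteria[["duplex_mismatches"]]))
    if (!isTRUE(ev$criteria[["duplex_mismatches"]])) fails <- TRUE
  }
  expect_true(fails)  # six mutations must eventually exceed four mismatches
  # lowering the star count never turns criterion 4 from fail to pass
  s <- fold_rna(ph$hairpin)
  was_fail <- FALSE
  for (star in c(10, 20, 21, 30, 100)) {
    ev <- evaluate_criteria(s, m1, ph$mir_len, mirna_reads = 100,
                            star_reads = star)
    if (was_fail) expect_false(isTRUE(ev$criteria[["read_ratio"]]))
    if (!isTRUE(ev$criteria[["read_ratio"]])) was_fail <- TRUE
  }
  expect_true(was_fail)
})

test_that("thermodynamic statistics follow their defining identities", {
  # AMFE from printed MFE and hairpin length
  ts <- thermo_stats(mfe = -92, hairpin_length = 258, gc_percent = 39.53)
  expect_equal(round(ts$amfe, 2), -35.66)
  # MFEI from printed AMFE and GC%
  ts <- thermo_stats(mfe = -55.9, hairpin_length = 126, gc_percent = 44.96,
                     amfe = -43.33)
  expect_equal(round(ts$mfei, 2), 0.96)
  # zero-energy case
  ts <- thermo_stats("ACGTACGT", mfe = 0)
  expect_equal(ts$amfe, 0)
  expect_equal(ts$mfei, 0)
  # GC computed from sequence
  ts <- thermo_stats("GGCCAATT", mfe = -1)
  expect_equal(ts$gc_percent, 50)
  # GC of zero leaves MFEI undefined and flagged
  ts <- thermo_stats("AATTAATT", mfe = -1)
  expect_false(ts$mfei_defined)
  expect_true(is.na(ts$mfei))
  expect_error(thermo_stats(mfe = 1, hairpin_length = 100, gc_percent = 50),
               "mfe")
})

test_that("discovery recovers a planted hairpin end to end", {
  set.seed(35)
  ph <- planted_hairpin()
  star0 <- 2 * nchar(ph$arm) + 8 - ph$offset - ph$mir_len + 2
  star <- substr(ph$hairpin, star0 + 1, star0 + ph$mir_len)
  tags <- data.frame(sequence = c(ph$mir, star), control = c(100L, 10L),
                     salt = c(50L, 5L))
  cands <- discover_precursors(tags, c(ctg = ph$contig), flank = 200)
  mine <- cands[cands$tag == ph$mir, ]
  expect_gte(nrow(mine), 1)
  expect_true(all(mine$valid))
  expect_equal(unique(mine$star_sequence), star)
  expect_equal(unique(mine$read_ratio), 10)
  expect_equal(unique(mine$rpm_control), 100 / 110 * 1e6)
})
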