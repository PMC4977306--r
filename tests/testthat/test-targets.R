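test_that("duplex scoring applies the penalty scheme with seed weighting", {
  mir <- "TGACAGAAGAGAGTGAGCAC"  # 20 nt
  # perfect complement scores 0
  expect_equal(score_duplex(mir, revcomp(mir))$expectation, 0)
  # single G:U at miRNA position 15 (outside the 2-13 seed): 0.5
  site <- revcomp(mir)
  # miRNA position 15 pairs site position 20 - 15 + 1 = 6
  m15 <- substr(mir, 15, 15)
  wobble <- c(G = "T", T = "G")[[m15]]  # target base giving G:U with m15
  substr(site, 6, 6) <- wobble
  sc <- score_duplex(mir, site)
  expect_equal(sc$expectation, 0.5)
  expect_equal(sc$classes[15], "wobble")
  # single mismatch at position 5 (seed): 1 * 1.5
  site <- revcomp(mir)
  m5 <- substr(mir, 5, 5)
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(chartr("ACGT", "TGCA", m5),
                   c(G = "T", T = "G", A = "", C = "")[[m5]]))[1]
  substr(site, 16, 16) <- bad
  expect_equal(score_duplex(mir, site)$expectation, 1.5)
  # length mismatch without gap annotation errors
  expect_error(score_duplex(mir, "ACGT"), "length mismatch")
})

test_that("gapped alignments are scored through explicit annotation", {
  # 4-nt toy duplex with one target-side gap outside the seed via a custom
  # seed range, checking the flat gap penalty
  sc <- score_duplex(alignment = list(mirna = "ACGT", target = "TGC-"),
                     seed_range = c(2, 3))
  expect_equal(sc$expectation, 2)  # one gap at position 4, weight 1
  sc <- score_duplex(alignment = list(mirna = "ACGT", target = "TG-A"),
                     seed_range = c(2, 3))
  expect_equal(sc$expectation, 3)  # gap at position 3 inside the seed: 2 * 1.5
})

test_that("expectation is monotone under added mismatches", {
  set.seed(41)
  for (r in 1:20) {
    mir <- random_rna(21)
    site <- revcomp(mir)
    prev <- score_duplex(mir, site)$expectation
    positions <- sample(21)
    for (p in positions[1:6]) {
      sp <- 21 - p + 1
      old <- substr(site, sp, sp)
      m <- substr(mir, p, p)
      repl <- setdiff(c("A", "C", "G", "T"), old)
      # any replacement (wobble or mismatch) can only increase the penalty
      substr(site, sp, sp) <- repl[sample(length(repl), 1)]
      now <- score_duplex(mir, site)$expectation
      expect_gte(now, prev - 1e-9)
      prev <- now
    }
  }
})

test_that("inhibition mode hinges on pairing at miRNA positions 10-11", {
  mir <- random_rna(21)
  perfect <- revcomp(mir)
  expect_equal(classify_inhibition(score_duplex(mir, perfect)), "cleavage")
  mismatch_at <- function(p) {
    site <- perfect
    sp <- 21 - p + 1
    m <- substr(mir, p, p)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", m),
                     c(G = "T", T = "G", A = "Z", C = "Z")[[m]]))[1]
    substr(site, sp, sp) <- bad
    site
  }
  expect_equal(classify_inhibition(score_duplex(mir, mismatch_at(10))),
               "translation")
  expect_equal(classify_inhibition(score_duplex(mir, mismatch_at(11))),
               "translation")
  expect_equal(classify_inhibition(score_duplex(mir, mismatch_at(3))),
               "cleavage")
})

test_that("scanning reports planted sites and suppresses weak ones", {
  set.seed(42)
  mir <- random_rna(21)
  tx1 <- paste0(random_rna(50), revcomp(mir), random_rna(50))
  hits <- scan_targets(mir, c(tx1 = tx1), mirna_name = "m1")
  expect_gte(nrow(hits), 1)
  best <- hits[1, ]
  expect_equal(best$expectation, 0)
  expect_equal(best$start, 51)
  expect_equal(best$end, 71)
  expect_equal(best$inhibition, "cleavage")
  expect_equal(best$region, "unknown")
  # one seed mismatch: expectation 1.5, still reported
  site <- revcomp(mir)
  m5 <- substr(mir, 5, 5)
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(chartr("ACGT", "TGCA", m5),
                   c(G = "T", T = "G", A = "Z", C = "Z")[[m5]]))[1]
  substr(site, 17, 17) <- bad
  tx2 <- paste0(random_rna(30), site, random_rna(30))
  hits2 <- scan_targets(mir, c(tx2 = tx2))
  expect_equal(hits2$expectation[1], 1.5)
  # three seed mismatches (4.5) are above the default 3.0 cutoff
  site3 <- revcomp(mir)
  for (p in c(4, 6, 8)) {
    sp <- 21 - p + 1
    m <- substr(mir, p, p)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", m),
                     c(G = "T", T = "G", A = "Z", C = "Z")[[m]]))[1]
    substr(site3, sp, sp) <- bad
  }
  tx3 <- paste0(strrep("A", 30), site3, strrep("A", 30))
  hits3 <- scan_targets(mir, c(tx3 = tx3))
  expect_false(any(hits3$start == 31))              # the 4.5 site is suppressed
  expect_true(all(hits3$expectation <= 3))
  # empty transcript set
  expect_equal(nrow(scan_targets(mir, character())), 0)
})

test_that("scanning agrees with a brute-force all-offsets scorer", {
  set.seed(43)
  mir <- random_rna(21)
  tx <- setNames(c(random_rna(300), paste0(random_rna(100), revcomp(mir),
                                           random_rna(100))), c("a", "b"))
  got <- scan_targets(mir, tx, max_expectation = 6)
  # independent: score every offset with a plain loop over characters
  pen_of <- function(mirv, sitev) {
    p <- 0
    for (i in seq_along(mirv)) {
      m <- mirv[i]; t <- sitev[length(sitev) - i + 1]
      cls <- if ((m == "A" && t == "T") || (m == "T" && t == "A") ||
                 (m == "C" && t == "G") || (m == "G" && t == "C")) 0
             else if ((m == "G" && t == "T") || (m == "T" && t == "G")) 0.5
             else 1
      p <- p + cls * (if (i >= 2 && i <= 13) 1.5 else 1)
    }
    p
  }
  mirv <- strsplit(mir, "")[[1]]
  for (id in names(tx)) {
    s <- strsplit(tx[[id]], "")[[1]]
    for (st in seq_len(length(s) - 20)) {
      e <- pen_of(mirv, s[st:(st + 20)])
      row <- got[got$transcript_id == id & got$start == st, ]
      if (e <= 6) {
        expect_equal(nrow(row), 1)
        expect_equal(row$expectation, e)
      } else {
        expect_equal(nrow(row), 0)
      }
    }
  }
})

test_that("site regions are labelled from ORF annotations", {
  mir <- random_rna(21)
  tx <- paste0(random_rna(60), revcomp(mir), random_rna(60))
  orf <- data.frame(transcript_id = "t", orf_start = 130, orf_end = 140)
  expect_equal(scan_targets(mir, c(t = tx), orf = orf)$region[1], "5' UTR")
  orf <- data.frame(transcript_id = "t", orf_start = 5, orf_end = 50)
  expect_equal(scan_targets(mir, c(t = tx), orf = orf)$region[1], "3' UTR")
  orf <- data.frame(transcript_id = "t", orf_start = 10, orf_end = 120)
  expect_equal(scan_targets(mir, c(t = tx), orf = orf)$region[1], "ORF")
})
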