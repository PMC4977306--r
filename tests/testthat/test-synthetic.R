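small_cfg <- function(...) synthetic_config(n_valid = 2L, decoys = c("mfe", "ratio"),
                                            n_background = 2L, ...)

test_that("generation is deterministic under a fixed seed", {
  a <- generate_synthetic(small_cfg(), seed = 7)
  b <- generate_synthetic(small_cfg(), seed = 7)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$reads, b$reads)
  expect_identical(a$degradome, b$degradome)
  expect_identical(a$ct, b$ct)
  c <- generate_synthetic(small_cfg(), seed = 8)
  expect_false(identical(a$contigs, c$contigs))
  # written files are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_synthetic(small_cfg(), seed = 7, out_dir = d1)
  generate_synthetic(small_cfg(), seed = 7, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(arm_len = 30L, mirna_offset = 20L),
               "arm too short")
  expect_error(synthetic_config(loop_len = 2L), "loop")
  expect_error(synthetic_config(mirna_offset = 1L), "overhang")
  expect_error(synthetic_config(decoys = "bulge"), "unknown decoy")
  expect_error(generate_synthetic(small_cfg()), "seed")
})

test_that("the clean read pool matches the planted counts and length mixture", {
  syn <- generate_synthetic(small_cfg(), seed = 11)
  # run the generated raw reads through the preprocess stage
  clean <- lapply(syn$reads, function(r)
    filter_reads(trim_adapter(r, syn$config$adapter), syn$contaminants))
  expect_equal(vapply(clean, length, numeric(1)), syn$clean_totals)
  res <- collapse_tags(clean)
  # noise-free mixture: every clean read is exactly mirna_len long
  for (p in res$profiles) {
    hist <- p$redundant_size_histogram
    expect_equal(sum(hist), p$total_clean_reads)
    expect_equal(unname(hist[as.character(syn$config$mirna_len)]),
                 p$total_clean_reads)
  }
  # planted RPM: count / clean total * 1e6, exactly
  hp <- syn$truth$hairpins[[1]]
  lib <- "control"
  idx <- match(hp$mirna, res$tags$sequence)
  expect_equal(compute_rpm(res$tags[[lib]][idx], syn$clean_totals[[lib]]),
               hp$mirna_counts[[lib]] / syn$clean_totals[[lib]] * 1e6)
  expect_equal(res$tags[[lib]][idx], hp$mirna_counts[[lib]])
})

test_that("every truth entry names the module it tests", {
  syn <- generate_synthetic(small_cfg(), seed = 12)
  entries <- c(syn$truth$hairpins, syn$truth$decoys, syn$truth$target_sites,
               syn$truth$degradome_peaks, syn$truth$ct_shifts,
               list(syn$truth$read_counts, syn$truth$length_mixture))
  mods <- vapply(entries, `[[`, "", "module")
  expect_true(all(mods %in% c("preprocess", "conserved_match",
                              "precursor_discovery", "target_predict",
                              "degradome", "expression")))
  expect_identical(syn$truth$seed, 12L)
})

test_that("planted hairpins pass discovery and decoys fail their criterion", {
  syn <- generate_synthetic(small_cfg(), seed = 13)
  clean <- lapply(syn$reads, function(r)
    filter_reads(trim_adapter(r, syn$config$adapter), syn$contaminants))
  tags <- collapse_tags(clean)$tags
  hairpin_contigs <- syn$contigs[grep("hairpin|decoy", names(syn$contigs))]
  cands <- discover_precursors(tags, hairpin_contigs)
  planted <- vapply(syn$truth$hairpins, `[[`, "", "mirna")
  valid_tags <- unique(cands$tag[cands$valid])
  expect_setequal(intersect(valid_tags, planted), planted)
  # the mfe decoy folds weakly; the ratio decoy fails the 5:1 rule
  for (d in syn$truth$decoys) {
    rows <- cands[cands$tag == d$mirna, ]
    expect_gte(nrow(rows), 1)
    expect_false(any(rows$valid))
    crit_col <- c(mfe = "crit_mfe", ratio = "crit_read_ratio")[[d$violation]]
    expect_false(any(rows[[crit_col]]))
  }
})

test_that("planted Ct shifts are recovered by the expression stage", {
  syn <- generate_synthetic(small_cfg(), seed = 14)
  res <- delta_delta_ct(syn$ct)
  for (shift in syn$truth$ct_shifts) {
    got <- res$fold_change[res$assay == shift$assay]
    expect_equal(got, shift$fold_change, tolerance = 0.1)
  }
})

test_that("generated files are consumable by the file-based readers", {
  dir <- withr::local_tempdir()
  syn <- generate_synthetic(small_cfg(), seed = 15, out_dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("transcriptome.fasta", "contaminants.fasta", "mature_reference.fasta",
      "degradome.fasta", "reads_control.fastq", "reads_salt.fastq",
      "ct_table.tsv", "truth.yaml")))))
  r <- read_reads_fastq(file.path(dir, "reads_control.fastq"))
  expect_equal(nrow(r), length(syn$reads$control))
  tx <- Biostrings::readDNAStringSet(file.path(dir, "transcriptome.fasta"))
  expect_equal(length(tx), length(syn$contigs))
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(length(truth$hairpins), 2)
  deg <- read_degradome_tags(file.path(dir, "degradome.fasta"),
                             syn$transcripts)
  pk <- syn$truth$degradome_peaks[[1]]
  got <- deg[deg$transcript_id == pk$transcript_id &
               deg$five_prime_position == pk$position, ]
  expect_equal(got$count, pk$count)
})
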