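#' Configuration for the synthetic-data generator
#'
#' Defaults describe a small but realistic two-library (control / salt)
#' experiment: 5 valid planted hairpins and 5 decoys that violate a named
#' criterion, 21-nt miRNAs inside 70-bp perfect stems (loop 8 nt), mature
#' read counts drawn log-uniformly between 20 and 200 per library with star
#' counts about a tenth of that (ratio around 10:1, comfortably above the
#' 5:1 criterion; ratio decoys get half the mature count as star reads),
#' 10 background contigs, a t/rRNA contaminant fraction, degradome tags
#' concentrated opposite miRNA position 10 with singleton background noise,
#' and Ct tables with per-assay treatment shifts.
#'
#' @param n_valid number of planted valid hairpins.
#' @param decoys character vector of violation names, one decoy each;
#'   supported: `"mfe"` (unstructured locus, hairpin MFE above -35) and
#'   `"ratio"` (star reads more than a fifth of mature reads).
#' @param mirna_len mature miRNA length (nt).
#' @param arm_len,loop_len stem arm and loop lengths of planted hairpins.
#' @param mirna_offset offset of the miRNA 5' end within the 5' arm (>= 2 so
#'   the 2-nt star overhang stays inside the precursor).
#' @param flank_len unstructured flank planted on each side of a hairpin.
#' @param n_background,background_len_range background contigs.
#' @param count_range log-uniform range of mature read counts per library.
#' @param star_divisor mature:star count divisor for valid hairpins.
#' @param n_contaminants,contaminant_count t/rRNA-like contaminant species
#'   and their per-library read count.
#' @param adapter 3' adapter appended to every synthetic raw read.
#' @param degradome_peak_count reads at each planted cleavage position.
#' @param degradome_noise singleton background tags per transcript.
#' @param ct_replicates,ct_sd qPCR replicates per condition and Ct noise.
#' @param libraries library labels.
#' @return a config list for [generate_synthetic()].
#' @export
synthetic_config <- function(n_valid = 5L,
                             decoys = c("mfe", "ratio", "mfe", "ratio", "mfe"),
                             mirna_len = 21L, arm_len = 70L, loop_len = 8L,
                             mirna_offset = 20L, flank_len = 200L,
                             n_background = 10L,
                             background_len_range = c(500L, 1500L),
                             count_range = c(20L, 200L), star_divisor = 10,
                             n_contaminants = 2L, contaminant_count = 30L,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             degradome_peak_count = 20L,
                             degradome_noise = 5L,
                             ct_replicates = 6L, ct_sd = 0.05,
                             libraries = c("control", "salt")) {
  cfg <- as.list(environment())
  if (cfg$n_valid < 1L) invalid_arg("counts must be >= 1")
  if (cfg$mirna_offset + cfg$mirna_len > cfg$arm_len)
    invalid_arg("hairpin arm too short for the miRNA (need offset + length <= arm)")
  if (cfg$mirna_offset < 2L)
    invalid_arg("mirna_offset must be >= 2 for the 2-nt star overhang")
  if (cfg$loop_len < 3L) invalid_arg("hairpin loop must be >= 3 nt")
  if (!all(cfg$decoys %in% c("mfe", "ratio")))
    invalid_arg("unknown decoy violation; use 'mfe' or 'ratio'")
  cfg
}

.rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## unstructured spacer: A/C only, so no base can pair with any other
.rand_ac <- function(n) .rand_dna(n, c("A", "C"))

.log_uniform_count <- function(range) {
  round(exp(stats::runif(1, log(range[1]), log(range[2]))))
}

#' Generate a fully specified synthetic input set with a truth object
#'
#' Builds a transcriptome with planted hairpin precursors (perfect stems with
#' unstructured A/C flanks, so the designed duplex is the unambiguous MFE
#' structure) and named-violation decoys, small-RNA libraries with mature and
#' star reads at the configured abundances plus adapters, length/ambiguity
#' junk and contaminant reads, degradome tags concentrated at the position
#' opposite miRNA position 10 of each planted target site, and a replicate
#' Ct table with planted treatment shifts. Regenerating with the same seed
#' reproduces all outputs byte-identically.
#'
#' @param config a list from [synthetic_config()].
#' @param seed integer random seed (required).
#' @param out_dir optional directory; when given, all input files (FASTQ /
#'   FASTA / TSV plus `truth.yaml`) are written there.
#' @return a list with the in-memory inputs and the truth:
#' \describe{
#'   \item{contigs}{named character vector (the synthetic transcriptome).}
#'   \item{reads}{named list per library of raw read sequences (with
#'     adapters and junk) — input to the preprocess stage.}
#'   \item{clean_totals}{named vector of planted 18–25 nt clean totals.}
#'   \item{reference}{mature reference data frame for the planted miRNAs.}
#'   \item{contaminants}{contaminant sequences.}
#'   \item{degradome}{data frame of degradome tags (sequence,
#'     transcript_id, five_prime_position, count).}
#'   \item{ct}{replicate Ct table.}
#'   \item{truth}{list of planted facts; every entry names the module it
#'     tests (`hairpins`, `decoys`, `target_sites`, `degradome_peaks`,
#'     `ct_shifts`, `read_counts`, `length_mixture`, `seed`).}
#' }
#' @export
generate_synthetic <- function(config = synthetic_config(), seed,
                               out_dir = NULL) {
  if (missing(seed)) invalid_arg("a seed is required")
  set.seed(as.integer(seed))
  cfg <- config
  libs <- cfg$libraries
  contigs <- character()
  hairpins <- list()
  decoys <- list()
  reads <- setNames(rep(list(character()), length(libs)), libs)

  add_reads <- function(lib, seq, count) {
    if (count > 0) reads[[lib]] <<- c(reads[[lib]], rep(seq, count))
  }

  ## --- planted valid hairpins -------------------------------------------
  for (i in seq_len(cfg$n_valid)) {
    repeat {
      arm <- .rand_dna(cfg$arm_len)
      mir <- substr(arm, cfg$mirna_offset + 1L,
                    cfg$mirna_offset + cfg$mirna_len)
      if (!grepl("[^ACGT]", mir) && !mir %in% vapply(hairpins, `[[`,
                                                     "", "mirna")) break
    }
    hp <- paste0(arm, .rand_ac(cfg$loop_len), revcomp(arm))
    strand <- if (i %% 2L == 1L) "+" else "-"
    contig <- paste0(.rand_ac(cfg$flank_len),
                     if (strand == "+") hp else revcomp(hp),
                     .rand_ac(cfg$flank_len))
    cid <- sprintf("hairpin_contig_%02d", i)
    contigs[cid] <- contig
    # star span in hairpin coordinates (0-based): the 2-nt 3'-overhang rule
    # puts the star 5' end at the partner of miRNA position L-2
    A <- cfg$arm_len; l <- cfg$loop_len; a <- cfg$mirna_offset
    star0 <- 2L * A + l - a - cfg$mirna_len + 2L
    star <- substr(hp, star0 + 1L, star0 + cfg$mirna_len)
    mc <- setNames(vapply(libs, function(x)
      .log_uniform_count(cfg$count_range), numeric(1)), libs)
    sc <- setNames(pmax(1, floor(mc / cfg$star_divisor)), libs)
    for (lib in libs) {
      add_reads(lib, mir, mc[[lib]])
      add_reads(lib, star, sc[[lib]])
    }
    hairpins[[i]] <- list(module = "precursor_discovery",
                          name = sprintf("syn-miR%d", i), contig_id = cid,
                          strand = strand, precursor = hp, mirna = mir,
                          star = star,
                          mirna_counts = as.list(mc), star_counts = as.list(sc),
                          expected_valid = TRUE)
  }

  ## --- decoys with a named violated criterion ---------------------------
  for (j in seq_along(cfg$decoys)) {
    viol <- cfg$decoys[j]
    cid <- sprintf("decoy_contig_%02d", j)
    if (viol == "mfe") {
      # unstructured A/C locus: the window folds with no pairs, MFE 0
      mir <- .rand_ac(cfg$mirna_len)
      contigs[cid] <- paste0(.rand_ac(cfg$flank_len), mir,
                             .rand_ac(cfg$flank_len))
      mc <- setNames(vapply(libs, function(x)
        .log_uniform_count(cfg$count_range), numeric(1)), libs)
      sc <- setNames(rep(0, length(libs)), libs)
      star <- NA_character_
    } else {
      # sound hairpin, but the star strand is sequenced too abundantly
      repeat {
        arm <- .rand_dna(cfg$arm_len)
        mir <- substr(arm, cfg$mirna_offset + 1L,
                      cfg$mirna_offset + cfg$mirna_len)
        if (!mir %in% c(vapply(hairpins, `[[`, "", "mirna"),
                        vapply(decoys, function(d) d$mirna %||% "", ""))) break
      }
      hp <- paste0(arm, .rand_ac(cfg$loop_len), revcomp(arm))
      contigs[cid] <- paste0(.rand_ac(cfg$flank_len), hp,
                             .rand_ac(cfg$flank_len))
      A <- cfg$arm_len; l <- cfg$loop_len; a <- cfg$mirna_offset
      star0 <- 2L * A + l - a - cfg$mirna_len + 2L
      star <- substr(hp, star0 + 1L, star0 + cfg$mirna_len)
      mc <- setNames(vapply(libs, function(x)
        .log_uniform_count(cfg$count_range), numeric(1)), libs)
      sc <- setNames(ceiling(mc / 2), libs)  # ratio ~2:1, below 5:1
    }
    for (lib in libs) {
      add_reads(lib, mir, mc[[lib]])
      if (!is.na(star)) add_reads(lib, star, sc[[lib]])
    }
    decoys[[j]] <- list(module = "precursor_discovery",
                        name = sprintf("syn-decoy%d", j), contig_id = cid,
                        violation = viol, mirna = mir, star = star,
                        mirna_counts = as.list(mc), star_counts = as.list(sc),
                        expected_valid = FALSE)
  }

  ## --- background contigs ------------------------------------------------
  for (b in seq_len(cfg$n_background)) {
    contigs[sprintf("bg_contig_%02d", b)] <-
      .rand_dna(sample(cfg$background_len_range[1]:cfg$background_len_range[2], 1))
  }

  ## clean totals before junk/contaminants are appended
  clean_totals <- vapply(reads, length, numeric(1))

  ## --- contaminants and junk reads (removed by the preprocess filters) ---
  contaminants <- vapply(seq_len(cfg$n_contaminants),
                         function(k) .rand_dna(sample(18:25, 1)), "")
  for (lib in libs) {
    for (ct in contaminants) add_reads(lib, ct, cfg$contaminant_count)
    add_reads(lib, .rand_dna(15L), 3L)              # too short
    add_reads(lib, .rand_dna(28L), 3L)              # too long
    add_reads(lib, paste0(.rand_dna(10L), "N", .rand_dna(10L)), 2L)  # ambiguous
  }

  ## raw reads carry the 3' adapter
  raw_reads <- lapply(reads, function(r) paste0(r, cfg$adapter))

  ## --- target transcripts and degradome tags -----------------------------
  transcripts <- character()
  target_sites <- list()
  deg_rows <- list()
  peaks <- list()
  for (i in seq_len(cfg$n_valid)) {
    mir <- hairpins[[i]]$mirna
    tid <- sprintf("target_tx_%02d", i)
    site_start <- 151L   # 1-based
    tx <- paste0(.rand_dna(site_start - 1L), revcomp(mir), .rand_dna(100L))
    transcripts[tid] <- tx
    site_end <- site_start + cfg$mirna_len - 1L
    cpos <- site_end - 10L                        # 0-based slice position
    target_sites[[i]] <- list(module = "target_predict",
                              mirna = hairpins[[i]]$name,
                              transcript_id = tid, start = site_start,
                              end = site_end, expectation = 0,
                              inhibition = "cleavage")
    deg_rows[[length(deg_rows) + 1L]] <- data.frame(
      sequence = substr(tx, cpos + 1L, cpos + 20L), transcript_id = tid,
      five_prime_position = cpos, count = cfg$degradome_peak_count)
    peaks[[i]] <- list(module = "degradome", transcript_id = tid,
                       position = cpos, count = cfg$degradome_peak_count,
                       mirna = hairpins[[i]]$name)
    noise_pos <- sample(setdiff(seq(0L, nchar(tx) - 21L), cpos),
                        cfg$degradome_noise)
    for (np in noise_pos)
      deg_rows[[length(deg_rows) + 1L]] <- data.frame(
        sequence = substr(tx, np + 1L, np + 20L), transcript_id = tid,
        five_prime_position = np, count = 1L)
  }
  # decoy transcripts: background noise only, must never be confirmed
  for (j in seq_len(2L)) {
    tid <- sprintf("decoy_tx_%02d", j)
    tx <- .rand_dna(300L)
    transcripts[tid] <- tx
    noise_pos <- sample(seq(0L, nchar(tx) - 21L), cfg$degradome_noise)
    for (np in noise_pos)
      deg_rows[[length(deg_rows) + 1L]] <- data.frame(
        sequence = substr(tx, np + 1L, np + 20L), transcript_id = tid,
        five_prime_position = np, count = 1L)
  }
  degradome <- do.call(rbind, deg_rows)
  row.names(degradome) <- NULL

  ## --- Ct table with planted shifts --------------------------------------
  ct_rows <- list()
  ct_shifts <- list()
  for (i in seq_len(cfg$n_valid)) {
    assay <- hairpins[[i]]$name
    fold <- round(stats::runif(1, -2, 2), 2)   # planted -ddCt
    for (cond in c("control", "salt")) {
      base <- if (cond == "control") 25 else 25 - fold
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        assay = assay, condition = cond, replicate = seq_len(cfg$ct_replicates),
        target_ct = base + stats::rnorm(cfg$ct_replicates, 0, cfg$ct_sd),
        control_ct = 20)
    }
    ct_shifts[[i]] <- list(module = "expression", assay = assay,
                           fold_change = fold)
  }
  ct <- do.call(rbind, ct_rows)
  row.names(ct) <- NULL

  reference <- data.frame(
    name = paste0(vapply(hairpins, `[[`, "", "name"), "a"),
    family = vapply(hairpins, `[[`, "", "name"),
    sequence = vapply(hairpins, `[[`, "", "mirna"))

  truth <- list(seed = as.integer(seed),
                hairpins = hairpins, decoys = decoys,
                target_sites = target_sites, degradome_peaks = peaks,
                ct_shifts = ct_shifts,
                read_counts = list(module = "preprocess",
                                   clean_totals = as.list(clean_totals)),
                length_mixture = list(module = "preprocess",
                                      mirna_len = cfg$mirna_len))

  out <- list(contigs = c(contigs, transcripts),
              transcripts = transcripts,
              reads = raw_reads, clean_totals = clean_totals,
              reference = reference, contaminants = contaminants,
              degradome = degradome, ct = ct, truth = truth,
              config = cfg)

  if (!is.null(out_dir)) .write_synthetic(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_synthetic <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wfa <- function(seqs, names, file) {
    s <- Biostrings::DNAStringSet(seqs)
    names(s) <- names
    Biostrings::writeXStringSet(s, file.path(out_dir, file))
  }
  wfa(unname(x$contigs), names(x$contigs), "transcriptome.fasta")
  wfa(unname(x$contaminants),
      paste0("contaminant_", seq_along(x$contaminants)), "contaminants.fasta")
  wfa(x$reference$sequence, x$reference$name, "mature_reference.fasta")
  deg_names <- sprintf("deg_%04d", seq_len(sum(x$degradome$count)))
  wfa(rep(x$degradome$sequence, x$degradome$count), deg_names,
      "degradome.fasta")
  for (lib in names(x$reads)) {
    r <- x$reads[[lib]]
    con <- file(file.path(out_dir, paste0("reads_", lib, ".fastq")), "w")
    writeLines(paste0("@", lib, "_", seq_along(r), "\n", r, "\n+\n",
                      strrep("I", nchar(r))), con)
    close(con)
  }
  write.table(x$ct, file.path(out_dir, "ct_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(x$truth, file.path(out_dir, "truth.yaml"))
  invisible(out_dir)
}
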