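#' Default pipeline configuration
#'
#' All thresholds default to the workflow's standard printed values: clean
#' read lengths 18–25 nt, at most 2 mismatches against the mature reference,
#' 200-nt precursor flanks, hairpin MFE at most -35 kcal/mol, miRNA:miRNA*
#' read ratio at least 5, target expectation at most 3.0, significance at
#' P <= 0.05.
#'
#' @param reads named list of FASTQ/FASTA paths, one per library.
#' @param transcriptome FASTA of transcriptome contigs.
#' @param contaminants optional FASTA of t/rRNA contaminant sequences.
#' @param mature_reference optional FASTA of mature miRNAs (conserved-family
#'   stage; skipped when `NULL`).
#' @param degradome optional FASTA of degradome 5'-end tags.
#' @param ct_table optional TSV of replicate Ct values.
#' @param out_dir report directory.
#' @param adapter 3' adapter to trim (`NULL` to skip trimming).
#' @param min_len,max_len,max_mismatches,flank,mfe_max,min_ratio,max_expectation,alpha
#'   stage thresholds.
#' @return a config list for [run_pipeline()]; round-trips through YAML
#'   unchanged.
#' @export
pipeline_config <- function(reads, transcriptome, contaminants = NULL,
                            mature_reference = NULL, degradome = NULL,
                            ct_table = NULL, out_dir = "halomir_out",
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            min_len = 18L, max_len = 25L,
                            max_mismatches = 2L, flank = 200L,
                            mfe_max = -35, min_ratio = 5,
                            max_expectation = 3, alpha = 0.05) {
  as.list(environment())
}

.require_input <- function(path, stage) {
  if (is.null(path)) return(FALSE)
  if (!file.exists(path))
    stop("file not found (stage ", stage, "): ", path, call. = FALSE)
  TRUE
}

#' Run the full discovery and profiling pipeline
#'
#' Ties the stages together: preprocess each library (trim, filter,
#' collapse, profile), assign conserved families and quantify them in RPM,
#' discover hairpin precursors on the transcriptome, predict targets of the
#' valid candidates, confirm cleavage against the degradome, and analyse
#' qPCR expression. All stage reports are written to `config$out_dir` as TSV
#' plus a run log recording every threshold applied. The run is a pure
#' function of its inputs: re-running the same config yields byte-identical
#' reports.
#'
#' @param config a list from [pipeline_config()] or a path to a YAML file of
#'   the same shape.
#' @return invisibly, a list with the in-memory results (`tags`, `profiles`,
#'   `families`, `rpm_comparison`, `candidates`, `targets`, `degradome`,
#'   `expression`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logline <- function(...) cat(..., "\n", sep = "", file = log_path,
                               append = TRUE)
  cat("", file = log_path)
  logline("halomir pipeline run")
  for (nm in c("adapter", "min_len", "max_len", "max_mismatches", "flank",
               "mfe_max", "min_ratio", "max_expectation", "alpha"))
    logline("threshold ", nm, " = ", cfg[[nm]] %||% "NULL")

  ## --- preprocess --------------------------------------------------------
  contam <- character()
  if (.require_input(cfg$contaminants, "preprocess"))
    contam <- as.character(Biostrings::readDNAStringSet(cfg$contaminants))
  clean <- list()
  for (lib in names(cfg$reads)) {
    .require_input(cfg$reads[[lib]], "preprocess") ||
      stop("file not found (stage preprocess): reads for ", lib,
           call. = FALSE)
    path <- cfg$reads[[lib]]
    r <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) read_reads_fastq(path)
         else read_reads_fasta(path)
    if (!is.null(cfg$adapter)) r <- trim_adapter(r, cfg$adapter)
    r <- filter_reads(r, contam, cfg$min_len, cfg$max_len)
    clean[[lib]] <- r$sequence
    logline("library ", lib, ": ", length(clean[[lib]]), " clean reads")
  }
  collapsed <- collapse_tags(clean)
  write_profile_tsv(collapsed$profiles,
                    file.path(cfg$out_dir, "library_profiles.tsv"))
  totals <- vapply(collapsed$profiles, `[[`, numeric(1), "total_clean_reads")

  ## --- conserved families ------------------------------------------------
  families <- NULL; rpm_cmp <- NULL
  if (.require_input(cfg$mature_reference, "conserved_match")) {
    reference <- read_mature_reference(cfg$mature_reference)
    families <- family_abundance(collapsed$tags, reference, totals,
                                 cfg$max_mismatches)
    write.table(families, file.path(cfg$out_dir, "family_rpm.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    libs <- setdiff(names(families), "family")
    if (length(libs) == 2) {
      rpm_cmp <- compare_rpm(families, libs[1], libs[2])
      write.table(rpm_cmp, file.path(cfg$out_dir, "family_comparison.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    logline("families quantified: ", nrow(families))
  }

  ## --- precursor discovery ----------------------------------------------
  .require_input(cfg$transcriptome, "precursor_discovery") ||
    stop("file not found (stage precursor_discovery): transcriptome",
         call. = FALSE)
  contigs <- Biostrings::readDNAStringSet(cfg$transcriptome)
  candidates <- discover_precursors(collapsed$tags, contigs, totals,
                                    flank = cfg$flank, mfe_max = cfg$mfe_max,
                                    min_ratio = cfg$min_ratio)
  if (nrow(candidates) > 0)
    write_candidate_tsv(candidates,
                        file.path(cfg$out_dir, "precursor_candidates.tsv"))
  logline("precursor candidates: ", nrow(candidates), "; valid: ",
          if (nrow(candidates)) sum(candidates$valid) else 0L)

  ## --- targets of valid candidates ---------------------------------------
  targets <- NULL
  if (nrow(candidates) > 0 && any(candidates$valid)) {
    valid_tags <- unique(candidates$tag[candidates$valid])
    tx <- setNames(as.character(contigs), names(contigs))
    tlist <- lapply(valid_tags, function(tg)
      scan_targets(tg, tx, cfg$max_expectation, mirna_name = tg))
    targets <- do.call(rbind, tlist)
    if (!is.null(targets) && nrow(targets) > 0)
      write.table(targets, file.path(cfg$out_dir, "target_sites.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    logline("target sites reported: ",
            if (is.null(targets)) 0L else nrow(targets))
  }

  ## --- degradome confirmation --------------------------------------------
  confirmations <- NULL
  if (!is.null(targets) && nrow(targets) > 0 &&
      .require_input(cfg$degradome, "degradome")) {
    tx <- setNames(as.character(contigs), names(contigs))
    deg <- read_degradome_tags(cfg$degradome, contigs)
    tplots <- lapply(split(deg, deg$transcript_id), function(d)
      build_tplot(d, nchar(tx[[d$transcript_id[1]]])))
    confirmations <- confirm_cleavage(targets, tplots)
    write.table(confirmations,
                file.path(cfg$out_dir, "degradome_confirmations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logline("cleavage sites confirmed: ", sum(confirmations$confirmed))
  }

  ## --- expression --------------------------------------------------------
  expression <- NULL
  if (.require_input(cfg$ct_table, "expression")) {
    expression <- delta_delta_ct(read_ct_table(cfg$ct_table),
                                 alpha = cfg$alpha)
    write.table(expression, file.path(cfg$out_dir, "expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logline("expression assays: ", nrow(expression))
  }

  invisible(list(tags = collapsed$tags, profiles = collapsed$profiles,
                 families = families, rpm_comparison = rpm_cmp,
                 candidates = candidates, targets = targets,
                 degradome = confirmations, expression = expression))
}
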