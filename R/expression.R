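#' Delta-delta-Ct relative expression from replicate qPCR Ct values
#'
#' For each assay, the internal-control-normalised threshold cycle is
#' `dCt = target_ct - control_ct` per replicate; the per-condition dCt is
#' the replicate mean. The fold change is `-ddCt = dCt(control) - dCt(treatment)`
#' and the relative expression `2^(-ddCt)`, so a value above 1 (fold change
#' above 0) means increased expression under treatment. Significance is a
#' two-sample t-test on the replicate dCt values — Welch by default, pooled
#' variance with `var_equal = TRUE`; no multiple-testing correction is
#' applied (per-assay asterisks at `alpha`).
#'
#' @param ct data frame with columns `assay`, `condition`, `replicate`,
#'   `target_ct`, `control_ct` (the internal control, e.g. U6 for miRNAs,
#'   a reference mRNA for targets).
#' @param control,treatment condition labels (defaults `"control"`, `"salt"`).
#' @param alpha significance level (default 0.05).
#' @param var_equal use the pooled-variance t-test (default `FALSE`: Welch).
#' @return data frame with one row per assay: `assay`, `dct_control`,
#'   `dct_treatment`, `fold_change` (= -ddCt), `relative_expression`
#'   (= 2^fold_change), `p_value`, `significant`. With fewer than 2
#'   replicates in either condition the p-value is `NA`.
#' @examples
#' ct <- data.frame(assay = "miRX",
#'                  condition = rep(c("control", "salt"), each = 3),
#'                  replicate = rep(1:3, 2),
#'                  target_ct = c(25, 25.1, 24.9, 23, 23.2, 22.8),
#'                  control_ct = 20)
#' delta_delta_ct(ct)
#' @export
delta_delta_ct <- function(ct, control = "control", treatment = "salt",
                           alpha = 0.05, var_equal = FALSE) {
  need <- c("assay", "condition", "replicate", "target_ct", "control_ct")
  if (!all(need %in% names(ct)))
    invalid_arg("ct table needs columns: ", paste(need, collapse = ", "))
  if (any(is.na(ct$control_ct)))
    invalid_arg("missing internal control Ct values")
  rows <- lapply(split(ct, ct$assay), function(a) {
    dct <- a$target_ct - a$control_ct
    dc <- dct[a$condition == control]
    dt <- dct[a$condition == treatment]
    if (length(dc) == 0 || length(dt) == 0)
      invalid_arg("assay ", a$assay[1], ": both conditions must be present")
    fold <- mean(dc) - mean(dt)
    p <- if (length(dc) >= 2 && length(dt) >= 2)
      tryCatch(t.test(dc, dt, var.equal = var_equal)$p.value,
               error = function(e) NA_real_)   # e.g. zero variance
    else NA_real_
    data.frame(assay = a$assay[1], dct_control = mean(dc),
               dct_treatment = mean(dt), fold_change = fold,
               relative_expression = 2^fold, p_value = p,
               significant = !is.na(p) & p <= alpha)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Compare family RPM between two conditions
#'
#' Linear and log2 ratios of treatment to control RPM with a direction label
#' under a configurable dead-band: a family is `"unchanged"` when its ratio
#' lies within `1 +/- dead_band`, else `"up"` or `"down"`. A family absent
#' from the control but present in the treatment yields an infinite ratio
#' and is flagged.
#'
#' @param abundance data frame from [family_abundance()] (`family` plus one
#'   RPM column per library).
#' @param control,treatment library column names (defaults `"control"`,
#'   `"salt"`).
#' @param dead_band relative dead-band for `"unchanged"` (default 0.1).
#' @return data frame with `family`, the two RPM columns, `ratio`,
#'   `log2_ratio`, `direction` and `flag_infinite`.
#' @export
compare_rpm <- function(abundance, control = "control", treatment = "salt",
                        dead_band = 0.1) {
  if (!all(c(control, treatment) %in% names(abundance)))
    invalid_arg("abundance table lacks the requested conditions")
  c_rpm <- abundance[[control]]
  t_rpm <- abundance[[treatment]]
  ratio <- ifelse(c_rpm > 0, t_rpm / c_rpm,
                  ifelse(t_rpm > 0, Inf, NA_real_))
  direction <- ifelse(is.na(ratio), "unchanged",
                      ifelse(ratio > 1 + dead_band, "up",
                             ifelse(ratio < 1 - dead_band, "down",
                                    "unchanged")))
  data.frame(family = abundance$family,
             control_rpm = c_rpm, treatment_rpm = t_rpm,
             ratio = ratio, log2_ratio = log2(ratio),
             direction = direction,
             flag_infinite = is.infinite(ratio))
}

#' Read a qPCR Ct table from TSV
#'
#' Expected columns: `assay`, `condition`, `replicate`, `target_ct`,
#' `control_ct`.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_ct_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
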