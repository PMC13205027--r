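#' Summarize one treatment arm
#'
#' Arm-level summary of a per-organoid measurement (relative change in
#' diameter, in percent, or ΔORR): the sample median and the sample standard
#' deviation (n - 1 denominator) over all organoids pooled across replicates.
#'
#' @param values Per-organoid measurements (>= 2 finite values).
#' @param line_id,treatment_label Identifiers.
#' @param modality `"diameter"` or `"ORR"`.
#' @return An object of class `"arm_summary"`: list with `line_id`,
#'   `treatment_label`, `modality`, `n`, `median`, `sd`, `values`.
#' @export
summarize_arm <- function(values, line_id = NA_character_,
                          treatment_label = NA_character_,
                          modality = c("diameter", "ORR")) {
  modality <- match.arg(modality)
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop("arm '", treatment_label, "' (", modality, "): need >= 2 finite ",
         "values, got ", length(values))
  }
  structure(list(
    line_id = line_id,
    treatment_label = treatment_label,
    modality = modality,
    n = length(values),
    median = stats::median(values),
    sd = stats::sd(values),
    values = values
  ), class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("<arm_summary %s/%s [%s]: n=%d, median=%.4g, sd=%.4g>\n",
              x$line_id, x$treatment_label, x$modality, x$n, x$median, x$sd))
  invisible(x)
}

#' Modified Glass's delta effect size
#'
#' The median-based Glass's delta used to score treatment response:
#' `mGΔ = (median_control - median_treatment) / sd_control`. Positive values
#' mean the treatment suppressed growth (diameter modality) or lowered the
#' ΔORR (ORR modality) relative to the untreated control. The statistic is
#' invariant under shifting all values by a constant and under rescaling all
#' values by a positive constant.
#'
#' @param control,treatment [summarize_arm()] objects for the same line and
#'   modality; the control arm must have positive standard deviation.
#' @return An object of class `"effect_size"`: list with `line_id`,
#'   `treatment_label`, `modality`, `mglass_delta`, `n_control`,
#'   `n_treatment`, and the arm medians and control SD used.
#' @export
mglass_delta <- function(control, treatment) {
  stopifnot(inherits(control, "arm_summary"), inherits(treatment, "arm_summary"))
  if (!identical(control$modality, treatment$modality)) {
    stop("control and treatment summaries have different modalities")
  }
  if (!is.na(control$line_id) && !is.na(treatment$line_id) &&
      control$line_id != treatment$line_id) {
    stop("control and treatment summaries come from different lines")
  }
  if (control$sd == 0) {
    stop("mGlass's delta undefined: control arm standard deviation is zero")
  }
  structure(list(
    line_id = control$line_id,
    treatment_label = treatment$treatment_label,
    modality = control$modality,
    mglass_delta = (control$median - treatment$median) / control$sd,
    n_control = control$n,
    n_treatment = treatment$n,
    median_control = control$median,
    median_treatment = treatment$median,
    sd_control = control$sd
  ), class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size %s/%s [%s]: mGlass's delta = %.3f (n=%d vs %d)>\n",
              x$line_id, x$treatment_label, x$modality, x$mglass_delta,
              x$n_control, x$n_treatment))
  invisible(x)
}

#' Compare two arms with a rank-sum test
#'
#' Two-sided Mann-Whitney rank-sum test on the per-organoid values; the
#' per-organoid distributions are typically skewed, so a nonparametric test
#' is the default. A Welch t-test is available behind the `method` flag.
#'
#' @param control,treatment Per-organoid values (>= 3 each).
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return Two-sided p-value, or `NA` with a warning when either arm has
#'   fewer than 3 finite values.
#' @export
compare_arms <- function(control, treatment, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  control <- control[is.finite(control)]
  treatment <- treatment[is.finite(treatment)]
  if (length(control) < 3 || length(treatment) < 3) {
    warning("compare_arms: fewer than 3 values in an arm; returning NA")
    return(NA_real_)
  }
  if (method == "wilcoxon") {
    stats::wilcox.test(control, treatment, exact = FALSE)$p.value
  } else {
    stats::t.test(control, treatment)$p.value
  }
}

#' Well-level comparator readouts
#'
#' The two conventional well-level response measures that the per-organoid
#' analysis is compared against: the CellTiter-Glo-style luminescence ratio
#' (mean treated-well / mean control-well) and the endpoint median Day-4
#' diameter (no Day-0 reference).
#'
#' @param treated_lum,control_lum Per-well luminescence values.
#' @param treated_d4_um Day-4 diameters of the treated arm's organoids.
#' @return List with `ctg_ratio` and `endpoint_median_d4`.
#' @export
well_level_readouts <- function(treated_lum, control_lum, treated_d4_um) {
  stopifnot(length(treated_lum) >= 1, length(control_lum) >= 1)
  list(
    ctg_ratio = mean(treated_lum) / mean(control_lum),
    endpoint_median_d4 = stats::median(treated_d4_um, na.rm = TRUE)
  )
}
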