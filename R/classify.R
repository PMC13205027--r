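#' Map a treatment label to its threshold class
#'
#' Chemotherapy regimens (5FU, oxaliplatin, SN38, FOLFOX, FOLFIRI) use the
#' `"chemo"` thresholds; radiation-containing regimens (XRT, 5FU+XRT) use the
#' `"chemoRT"` thresholds.
#'
#' @param treatment_label Treatment label.
#' @param class_map Named character vector mapping labels to classes;
#'   override to extend the default table.
#' @return `"chemo"` or `"chemoRT"`.
#' @export
treatment_class <- function(treatment_label,
                            class_map = default_class_map()) {
  if (!treatment_label %in% names(class_map)) {
    stop("unknown treatment '", treatment_label, "'; known labels: ",
         paste(names(class_map), collapse = ", "))
  }
  unname(class_map[[treatment_label]])
}

#' @rdname treatment_class
#' @export
default_class_map <- function() {
  c("5FU" = "chemo", oxaliplatin = "chemo", SN38 = "chemo",
    FOLFOX = "chemo", FOLFIRI = "chemo",
    XRT = "chemoRT", "5FU+XRT" = "chemoRT")
}

#' Response-classification threshold presets
#'
#' Validated mGlass's delta cutoffs for calling an arm treatment-sensitive or
#' treatment-resistant, per modality and treatment class, with explicit
#' boundary inclusivity:
#'
#' * `"methods"` (default): diameter/chemo sensitive at 1.25 or higher,
#'   resistant at 0.75 or lower; diameter/chemoRT sensitive at 1 or higher,
#'   resistant at 0 or lower; ΔORR/chemo sensitive above 1.5, resistant below
#'   0; ΔORR/chemoRT sensitive above 1, resistant below 0.
#' * `"results"`: identical except the diameter/chemoRT row uses sensitive
#'   above 1 and resistant below 0.5 (an alternative chemoradiation cutoff
#'   set reported alongside the default); both are shipped because the two
#'   reported variants genuinely differ.
#'
#' @param name Preset name.
#' @return A data.frame of class `"threshold_set"` with columns `modality`,
#'   `treatment_class`, `sensitive_cutoff`, `sensitive_inclusive`,
#'   `resistant_cutoff`, `resistant_inclusive`.
#' @export
threshold_presets <- function(name = c("methods", "results")) {
  name <- match.arg(name)
  ts <- data.frame(
    modality = c("diameter", "diameter", "ORR", "ORR"),
    treatment_class = c("chemo", "chemoRT", "chemo", "chemoRT"),
    sensitive_cutoff = c(1.25, 1, 1.5, 1),
    sensitive_inclusive = c(TRUE, TRUE, FALSE, FALSE),
    resistant_cutoff = c(0.75, 0, 0, 0),
    resistant_inclusive = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  if (name == "results") {
    i <- ts$modality == "diameter" & ts$treatment_class == "chemoRT"
    ts$sensitive_inclusive[i] <- FALSE
    ts$resistant_cutoff[i] <- 0.5
    ts$resistant_inclusive[i] <- FALSE
  }
  stopifnot(all(ts$sensitive_cutoff >= ts$resistant_cutoff))
  structure(ts, class = c("threshold_set", "data.frame"), preset = name)
}

#' Read or write a threshold set as JSON
#'
#' Threshold tables round-trip through a JSON config (rows of modality,
#' treatment class, cutoffs and inclusivity flags, plus the preset name), so
#' the exact cutoffs used by a run can be serialized alongside its results
#' and alternative cutoff sets can be supplied from a file.
#'
#' @param thresholds A [threshold_presets()]-shaped data.frame.
#' @param path JSON file path.
#' @return `write_thresholds_json()` returns `path` invisibly;
#'   `read_thresholds_json()` returns a `threshold_set` data.frame.
#' @export
write_thresholds_json <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "data.frame"))
  jsonlite::write_json(
    list(preset = attr(thresholds, "preset"),
         thresholds = as.data.frame(thresholds)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- obj$thresholds
  need <- c("modality", "treatment_class", "sensitive_cutoff",
            "sensitive_inclusive", "resistant_cutoff", "resistant_inclusive")
  stopifnot(all(need %in% names(ts)))
  if (!all(ts$sensitive_cutoff >= ts$resistant_cutoff)) {
    stop("invalid thresholds: sensitive cutoff below resistant cutoff")
  }
  structure(ts[need], class = c("threshold_set", "data.frame"),
            preset = obj$preset)
}

#' Classify an arm's treatment response from its effect size
#'
#' Applies the treatment-class thresholds to an mGlass's delta: `"sensitive"`
#' if it passes the sensitive cutoff, `"resistant"` if it passes the
#' resistant cutoff, `"intermediate"` otherwise. The category is monotone
#' non-decreasing in the effect size.
#'
#' @param effect An [mglass_delta()] `effect_size` object, or a bare numeric
#'   mGlass's delta (then `modality` and `treatment_label` are required).
#' @param thresholds A [threshold_presets()] table.
#' @param modality,treatment_label Used when `effect` is numeric.
#' @param class_map Treatment-label to class map, see [treatment_class()].
#' @return `"sensitive"`, `"intermediate"` or `"resistant"`.
#' @export
classify_response <- function(effect, thresholds = threshold_presets(),
                              modality = NULL, treatment_label = NULL,
                              class_map = default_class_map()) {
  if (inherits(effect, "effect_size")) {
    modality <- effect$modality
    treatment_label <- effect$treatment_label
    effect <- effect$mglass_delta
  }
  stopifnot(is.numeric(effect), length(effect) == 1,
            !is.null(modality), !is.null(treatment_label))
  cls <- treatment_class(treatment_label, class_map)
  row <- thresholds[thresholds$modality == modality &
                      thresholds$treatment_class == cls, ]
  if (nrow(row) != 1) {
    stop("no threshold row for modality '", modality, "', class '", cls, "'")
  }
  pass_hi <- if (row$sensitive_inclusive) effect >= row$sensitive_cutoff
             else effect > row$sensitive_cutoff
  pass_lo <- if (row$resistant_inclusive) effect <= row$resistant_cutoff
             else effect < row$resistant_cutoff
  if (pass_hi) "sensitive" else if (pass_lo) "resistant" else "intermediate"
}

#' Combine diameter and ΔORR response categories
#'
#' Most-sensitive-wins rule (`sensitive` > `intermediate` > `resistant`): the
#' ΔORR modality can upgrade an intermediate diameter call, never downgrade a
#' sensitive one. With one modality missing (`NA`), the other is returned.
#' Commutative and idempotent.
#'
#' @param diam_category,orr_category Categories from [classify_response()],
#'   or `NA`.
#' @return Combined category (or `NA` if both are missing).
#' @export
combine_modalities <- function(diam_category, orr_category) {
  lv <- c("resistant", "intermediate", "sensitive")
  chk <- function(x) stopifnot(is.na(x) || x %in% lv)
  chk(diam_category); chk(orr_category)
  if (is.na(diam_category)) return(orr_category)
  if (is.na(orr_category)) return(diam_category)
  lv[max(match(diam_category, lv), match(orr_category, lv))]
}

#' RECIST v1.1 target-lesion response category from SLD
#'
#' Sum-of-longest-diameters rules: complete response (CR) when the post SLD
#' is zero; progressive disease (PD) when the SLD increased by at least 20%
#' and by at least 5 mm absolute; partial response (PR) when the SLD
#' decreased by at least 30%; stable disease (SD) otherwise.
#'
#' @param sld_pre,sld_post SLD in mm before/after treatment (vectorized).
#' @return Character vector: `"CR"`, `"PR"`, `"SD"` or `"PD"`.
#' @export
recist_category <- function(sld_pre, sld_post) {
  if (any(sld_pre <= 0)) stop("recist_category: sld_pre must be > 0")
  if (any(sld_post < 0)) stop("recist_category: sld_post must be >= 0")
  pct <- 100 * (sld_post - sld_pre) / sld_pre
  ifelse(sld_post == 0, "CR",
    ifelse(pct >= 20 & (sld_post - sld_pre) >= 5, "PD",
      ifelse(pct <= -30, "PR", "SD")))
}

#' Concordance between predicted and clinical response
#'
#' Cross-tabulates the organoid-predicted category (sensitive / intermediate
#' / resistant) against the clinical RECIST category (CR / PR / SD / PD) and
#' computes the per-predicted-category clinical response rate, where clinical
#' response means partial or complete response (PR or CR; SD excluded).
#'
#' @param predictions data.frame with `subject_id` and `predicted`.
#' @param clinical data.frame with `subject_id` and either `recist` or both
#'   `sld_pre` and `sld_post` (then RECIST is derived via
#'   [recist_category()]).
#' @return An object of class `"concordance_table"`: `counts` (3 x 4 matrix,
#'   rows sensitive/intermediate/resistant, columns CR/PR/SD/PD),
#'   `response_rate` (per-row PR+CR fraction; `NA` for empty rows) and `n`.
#' @export
concordance_table <- function(predictions, clinical) {
  stopifnot(all(c("subject_id", "predicted") %in% names(predictions)))
  if (!"recist" %in% names(clinical)) {
    stopifnot(all(c("sld_pre", "sld_post") %in% names(clinical)))
    clinical$recist <- recist_category(clinical$sld_pre, clinical$sld_post)
  }
  miss_p <- setdiff(predictions$subject_id, clinical$subject_id)
  miss_c <- setdiff(clinical$subject_id, predictions$subject_id)
  if (length(miss_p) || length(miss_c) ||
      anyDuplicated(predictions$subject_id) || anyDuplicated(clinical$subject_id)) {
    stop("subject IDs do not match 1:1; unmatched: ",
         paste(c(miss_p, miss_c), collapse = ", "))
  }
  clinical <- clinical[match(predictions$subject_id, clinical$subject_id), ]
  pred_lv <- c("sensitive", "intermediate", "resistant")
  rec_lv <- c("CR", "PR", "SD", "PD")
  stopifnot(all(predictions$predicted %in% pred_lv),
            all(clinical$recist %in% rec_lv))
  counts <- table(factor(predictions$predicted, pred_lv),
                  factor(clinical$recist, rec_lv))
  counts <- unclass(as.matrix(counts))
  n_row <- rowSums(counts)
  rate <- ifelse(n_row > 0, (counts[, "CR"] + counts[, "PR"]) / n_row, NA_real_)
  structure(list(counts = counts, response_rate = rate, n = sum(counts)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Concordance of organoid-predicted vs clinical response (n =", x$n, ")\n")
  tab <- cbind(x$counts, `response rate` = round(100 * x$response_rate, 1))
  print(tab)
  invisible(x)
}
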