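#' Run the full imaging pipeline over a synthetic cohort
#'
#' Executes simulate -> render -> segment -> measure -> track -> redox for
#' every arm of a cohort: generates the ground-truth organoid table, renders
#' each (arm, replicate, field) at Day 0 and Day 4 with a deterministic
#' per-field noise seed derived from the master seed, segments and measures
#' every field, pairs detections across days by nearest centroid, and
#' assembles the canonical per-organoid record table.
#'
#' @param spec A [cohort_spec()].
#' @param channel_params A [channel_params()] list (default parameters when
#'   `NULL`).
#' @param params A [seg_params()] list.
#' @param edge_width_px Leading-edge width (px) for the ORR measurement.
#' @param max_shift_um Pairing acceptance radius (um).
#' @return List of class `"cohort_run"`: `records` (one row per tracked
#'   organoid: `organoid_id` NA for detections, `line_id`, `arm`,
#'   `replicate`, `field_index`, `d0_um`, `d4_um`, `rel_change_pct`, `orr0`,
#'   `orr4`, `delta_orr`, `paired`, `shift_um`), `truth` (the
#'   [generate_cohort()] table), `n_excluded_undefined_orr`, and `spec`.
#' @export
process_cohort <- function(spec, channel_params = NULL,
                           params = seg_params(), edge_width_px = 20,
                           max_shift_um = 150) {
  if (is.null(channel_params)) channel_params <- orgresponse::channel_params()
  truth <- generate_cohort(spec)
  records <- vector("list", length(spec$arms))
  n_undef <- 0L
  for (a in seq_along(spec$arms)) {
    arm <- spec$arms[[a]]$treatment_label
    sub <- truth[truth$arm == arm, , drop = FALSE]
    fields <- unique(sub[c("replicate", "field_index")])
    det0 <- vector("list", nrow(fields))
    det4 <- vector("list", nrow(fields))
    for (i in seq_len(nrow(fields))) {
      fsub <- sub[sub$replicate == fields$replicate[i] &
                    sub$field_index == fields$field_index[i], , drop = FALSE]
      stream <- ((a * 100 + fields$replicate[i]) * 100 + fields$field_index[i]) * 2
      f0 <- render_field(fsub, day = 0, spec, channel_params,
                         seed = child_seed(spec$seed, stream))
      f4 <- render_field(fsub, day = 4, spec, channel_params,
                         seed = child_seed(spec$seed, stream + 1))
      det0[[i]] <- measure_field(f0, edge_width_px = edge_width_px,
                                 params = params)
      det4[[i]] <- measure_field(f4, edge_width_px = edge_width_px,
                                 params = params)
    }
    det0 <- do.call(rbind, det0)
    det4 <- do.call(rbind, det4)
    paired <- pair_organoids(det0, det4, max_shift_um)
    undef <- is.na(paired$orr_d0) | (paired$paired & is.na(paired$orr_d4))
    n_undef <- n_undef + sum(undef)
    records[[a]] <- data.frame(
      line_id = spec$line_id,
      arm = arm,
      replicate = paired$replicate_d0,
      field_index = paired$field_index_d0,
      x_um = paired$x_um_d0,
      y_um = paired$y_um_d0,
      d0_um = paired$diameter_um_d0,
      d4_um = paired$diameter_um_d4,
      rel_change_pct = ifelse(paired$paired,
                              relative_change(paired$diameter_um_d0,
                                              paired$diameter_um_d4),
                              NA_real_),
      orr0 = paired$orr_d0,
      orr4 = paired$orr_d4,
      delta_orr = ifelse(paired$paired & !undef,
                         delta_orr(paired$orr_d0, paired$orr_d4),
                         NA_real_),
      paired = paired$paired,
      shift_um = paired$shift_um,
      stringsAsFactors = FALSE
    )
  }
  structure(list(records = do.call(rbind, records), truth = truth,
                 n_excluded_undefined_orr = n_undef, spec = spec),
            class = "cohort_run")
}

#' Effect sizes for every treated arm of a cohort run
#'
#' Summarises each arm (pooling organoids across replicates) and computes the
#' mGlass's delta of the treated arms against the control arm for both
#' modalities (relative change in diameter, ΔORR), plus the two-sided
#' rank-sum p-value.
#'
#' @param records The `records` table of [process_cohort()] (or any
#'   data.frame with `line_id`, `arm`, `rel_change_pct`, `delta_orr`).
#' @param control_label Label of the control arm.
#' @return data.frame with one row per (treated arm, modality): `line_id`,
#'   `treatment_label`, `modality`, `n_control`, `n_treatment`,
#'   `median_control`, `median_treatment`, `sd_control`, `mglass_delta`,
#'   `p_value`.
#' @export
effect_sizes_from_records <- function(records, control_label = "control") {
  stopifnot(control_label %in% records$arm)
  treated <- setdiff(unique(records$arm), control_label)
  line <- records$line_id[1]
  rows <- list()
  for (arm in treated) {
    for (mod in c("diameter", "ORR")) {
      col <- if (mod == "diameter") "rel_change_pct" else "delta_orr"
      vc <- records[[col]][records$arm == control_label]
      vt <- records[[col]][records$arm == arm]
      sc <- summarize_arm(vc, line, control_label, mod)
      st <- summarize_arm(vt, line, arm, mod)
      es <- mglass_delta(sc, st)
      rows[[length(rows) + 1L]] <- data.frame(
        line_id = line, treatment_label = arm, modality = mod,
        n_control = sc$n, n_treatment = st$n,
        median_control = sc$median, median_treatment = st$median,
        sd_control = sc$sd, mglass_delta = es$mglass_delta,
        p_value = compare_arms(vc, vt), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Generative presets reproducing the reported organoid lines
#'
#' Arm parameterisations for three organoid lines whose arm medians and
#' effect sizes are reported in the validation study this package
#' re-implements: LARC12 (control / FOLFOX / 5FU+XRT), LARC7 (control /
#' FOLFOX) and CRC8 (control / FOLFIRI). Growth-law medians are the printed
#' per-arm medians of relative change in diameter; the control-arm SD is
#' solved from the printed effect-size identity (e.g. 74.6 / 1.32 = 56.6 for
#' LARC12) and treated arms reuse it, since treated-arm SDs do not enter the
#' statistic and are not reported. ΔORR laws use the printed LARC12 medians
#' (control 0.046, FOLFOX 0.026, implied SD 0.02 / 0.47); for LARC7 and CRC8
#' the ΔORR arm medians are not reported, so a stand-in control median of
#' 0.046 with SD 0.04 is used and the treated median is solved from the
#' printed ΔORR effect size. Stand-in choices are documented in the methods
#' vignette.
#'
#' @param line_id One of `"LARC12"`, `"LARC7"`, `"CRC8"`.
#' @param n_per_arm Organoids per arm.
#' @return List of [arm_spec()] objects (first element is the control arm),
#'   with attribute `expected_effects`: data.frame of the generative
#'   (printed) effect sizes per treated arm and modality.
#' @export
line_presets <- function(line_id = c("LARC12", "LARC7", "CRC8"),
                         n_per_arm = 500) {
  line_id <- match.arg(line_id)
  n <- n_per_arm
  mk <- function(label, g_med, g_sd, do_med, do_sd, viab) {
    arm_spec(label, n,
             growth_pct_law = law("normal", mean = g_med, sd = g_sd),
             delta_orr_law = law("normal", mean = do_med, sd = do_sd),
             viability_factor = viab)
  }
  if (line_id == "LARC12") {
    sd_d <- 56.6              # shared control SD implied by both identities
    sd_o <- (0.046 - 0.026) / 0.47
    arms <- list(
      mk("control", 64.0, sd_d, 0.046, sd_o, 1),
      mk("FOLFOX", -10.6, sd_d, 0.026, sd_o, 0.6),
      mk("5FU+XRT", 17.5, sd_d, 0.046, sd_o, 0.8)
    )
    exp_eff <- data.frame(
      treatment_label = c("FOLFOX", "FOLFOX", "5FU+XRT"),
      modality = c("diameter", "ORR", "diameter"),
      expected = c((64.0 + 10.6) / sd_d, 0.47, (64.0 - 17.5) / sd_d)
    )
  } else if (line_id == "LARC7") {
    sd_d <- (14.5 + 9.4) / 0.92
    sd_o <- 0.04              # stand-in; treated median solved from mGΔ 1.26
    arms <- list(
      mk("control", 14.5, sd_d, 0.046, sd_o, 1),
      mk("FOLFOX", -9.4, sd_d, 0.046 - 1.26 * sd_o, sd_o, 0.6)
    )
    exp_eff <- data.frame(
      treatment_label = c("FOLFOX", "FOLFOX"),
      modality = c("diameter", "ORR"),
      expected = c(0.92, 1.26)
    )
  } else {
    sd_d <- (70.3 - 22.4) / 1.26
    sd_o <- 0.04              # stand-in; treated median solved from mGΔ 1.08
    arms <- list(
      mk("control", 70.3, sd_d, 0.046, sd_o, 1),
      mk("FOLFIRI", 22.4, sd_d, 0.046 - 1.08 * sd_o, sd_o, 0.65)
    )
    exp_eff <- data.frame(
      treatment_label = c("FOLFIRI", "FOLFIRI"),
      modality = c("diameter", "ORR"),
      expected = c(1.26, 1.08)
    )
  }
  attr(arms, "expected_effects") <- exp_eff
  arms
}

#' Recover printed effect sizes through the full imaging pipeline
#'
#' For one preset line, builds a reduced-field cohort with `n_per_arm`
#' organoids per arm, runs the complete pipeline (render, segment, track,
#' measure, ΔORR, effect sizes) once per seed, and averages the recovered
#' mGlass's delta over seeds.
#'
#' @param line_id Preset line, see [line_presets()].
#' @param n_per_arm Organoids per arm (default 500).
#' @param seeds Integer vector of master seeds (default 5 seeds).
#' @param params Segmentation parameters. The default lowers `min_area_um2`
#'   to 40 um^2: organoids that respond strongly shrink far below the general
#'   2000 um^2 detection default by Day 4, and dropping those remnants would
#'   censor exactly the strongest responders and bias the treated-arm median
#'   upward. The synthetic phantoms are high-contrast, so the small floor
#'   admits no noise objects.
#' @return data.frame per (treated arm, modality): recovered mean
#'   `mglass_delta`, the generative `expected` value, and `n_per_arm`.
#' @export
recover_effect_sizes <- function(line_id, n_per_arm = 500, seeds = 1:5,
                                 params = seg_params(min_area_um2 = 40)) {
  geom <- reduced_field_spec()
  arms <- line_presets(line_id, n_per_arm)
  expected <- attr(arms, "expected_effects")
  per_seed <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    spec <- cohort_spec(
      line_id, arms,
      fields_per_replicate = 5,
      replicates = ceiling(n_per_arm / (5 * 25)),
      field_size_px = geom$field_size_px,
      pixel_size = geom$pixel_size,
      grid_dim = 5,
      seed = seeds[i]
    )
    run <- process_cohort(spec, params = params)
    es <- effect_sizes_from_records(run$records)
    per_seed[[i]] <- es[c("treatment_label", "modality", "mglass_delta")]
  }
  all <- do.call(rbind, per_seed)
  agg <- stats::aggregate(mglass_delta ~ treatment_label + modality, all, mean)
  out <- merge(expected, agg, by = c("treatment_label", "modality"))
  out$line_id <- line_id
  out$n_per_arm <- n_per_arm
  out[c("line_id", "treatment_label", "modality", "expected",
        "mglass_delta", "n_per_arm")]
}
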