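#' Specify one treatment arm of a synthetic cohort
#'
#' Each arm carries the generative laws for its organoids' baseline longest
#' diameter, true percent growth over the 4-day window, baseline optical redox
#' ratio (ORR), and true per-organoid change in ORR, plus a well-viability
#' factor used by the CellTiter-Glo-style luminescence proxy.
#'
#' @param treatment_label Arm label, e.g. `"control"`, `"FOLFOX"`, `"5FU+XRT"`.
#' @param n_organoids Number of organoids in the arm (>= 1).
#' @param d0_diameter_law Law for Day-0 longest diameter, in micrometres.
#' @param growth_pct_law Law for true relative change in diameter, in percent.
#'   Draws are truncated below at -95 so Day-4 diameters stay positive.
#' @param orr0_law Law for Day-0 ORR; draws are clipped to \[0.01, 0.99\].
#' @param delta_orr_law Law for the true per-organoid change in ORR.
#' @param viability_factor Fraction in \[0, 1\] scaling the simulated well
#'   luminescence (ATP proxy) of this arm's organoids.
#' @param dropout_rate Probability that an organoid is absent at Day 4
#'   (attrition); default 0.
#' @return An object of class `"arm_spec"`.
#' @export
arm_spec <- function(treatment_label,
                     n_organoids,
                     d0_diameter_law = law("lognormal", median = 200, sdlog = 0.15),
                     growth_pct_law = law("normal", mean = 64, sd = 56.6),
                     orr0_law = law("normal", mean = 0.55, sd = 0.05),
                     delta_orr_law = law("normal", mean = 0.046, sd = 0.04),
                     viability_factor = 1,
                     dropout_rate = 0) {
  stopifnot(is.character(treatment_label), length(treatment_label) == 1L,
            n_organoids >= 1,
            viability_factor >= 0, viability_factor <= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(
    treatment_label = treatment_label,
    n_organoids = as.integer(n_organoids),
    d0_diameter_law = d0_diameter_law,
    growth_pct_law = growth_pct_law,
    orr0_law = orr0_law,
    delta_orr_law = delta_orr_law,
    viability_factor = viability_factor,
    dropout_rate = dropout_rate
  ), class = "arm_spec")
}

#' Specify a synthetic imaging cohort for one organoid line
#'
#' Describes the dish/imaging geometry and the treatment arms of one organoid
#' line. Organoids are placed on a regular grid emulating gridded glass
#' dishes: each field is divided into `grid_dim` x `grid_dim` cells and each
#' organoid occupies one cell at both imaging days, so masks never overlap and
#' re-identification across days is unambiguous.
#'
#' The default geometry is the full-resolution field (2044 x 2048 px at
#' 1.634 um/px, i.e. a 3.34 mm x 3.34 mm dish area, five fields per replicate,
#' three replicates). [reduced_field_spec()] gives a coarser-sampled variant of
#' the same physical geometry for large simulations.
#'
#' @param line_id Organoid line identifier, e.g. `"LARC12"`.
#' @param arms List of [arm_spec()] objects (non-empty).
#' @param fields_per_replicate Fields of view imaged per replicate well.
#' @param replicates Technical replicate wells per arm.
#' @param field_size_px Integer vector `(rows, cols)` of the field in pixels.
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param grid_dim Grid cells per field side (placement lattice).
#' @param seed Master seed; all per-arm and per-field child streams derive
#'   from it, so identical specs reproduce identical cohorts and images.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(line_id,
                        arms,
                        fields_per_replicate = 5,
                        replicates = 3,
                        field_size_px = c(2044L, 2048L),
                        pixel_size = 1.634,
                        grid_dim = 5,
                        seed = 1L) {
  if (inherits(arms, "arm_spec")) arms <- list(arms)
  stopifnot(length(arms) >= 1, all(vapply(arms, inherits, TRUE, "arm_spec")),
            pixel_size > 0, fields_per_replicate >= 1, replicates >= 1,
            length(field_size_px) == 2, all(field_size_px >= 64),
            grid_dim >= 1)
  labels <- vapply(arms, `[[`, "", "treatment_label")
  if (anyDuplicated(labels)) stop("duplicate treatment labels in arms")
  structure(list(
    line_id = line_id,
    arms = arms,
    fields_per_replicate = as.integer(fields_per_replicate),
    replicates = as.integer(replicates),
    field_size_px = as.integer(field_size_px),
    pixel_size = pixel_size,
    grid_dim = as.integer(grid_dim),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Reduced-field imaging geometry
#'
#' Same 3.34 mm physical field as the default geometry but sampled 4x coarser
#' (512 x 512 px at 6.536 um/px). Used for large simulation studies where the
#' quantities of interest (diameters of order 100 um and mask-mean intensity
#' ratios) are insensitive to the finer sampling.
#'
#' @return A list with `field_size_px` and `pixel_size` suitable for splicing
#'   into [cohort_spec()].
#' @export
reduced_field_spec <- function() {
  list(field_size_px = c(512L, 512L), pixel_size = 6.536)
}

grid_cell_um <- function(spec) {
  min(spec$field_size_px) / spec$grid_dim * spec$pixel_size
}

#' Generate the ground-truth organoid table for a cohort
#'
#' Samples every arm's organoids from its generative laws and assigns each to
#' a grid cell in a (replicate, field) pair. Day-4 positions are the Day-0
#' positions plus a small drift (organoids are embedded in gel). To keep
#' rendered masks strictly inside their grid cells (so they can never
#' overlap), Day-0 diameters are capped at 45% and Day-4 diameters at 92% of
#' the grid pitch; under the default laws and geometry these caps bind for
#' well under 1% of organoids, so the generative medians and SDs are
#' realized faithfully.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with one row per organoid: identifiers
#'   (`organoid_id`, `line_id`, `arm`, `replicate`, `field_index`,
#'   `cell_row`, `cell_col`), pixel centres at both days (`x0_px`, `y0_px`,
#'   `x4_px`, `y4_px`), true diameters `d0_um`, `d4_um`, true growth
#'   `growth_pct`, true ORRs `orr0`, `orr4`, `delta_orr`, per-organoid
#'   `viability`, and the attrition flag `present_day4`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cell_um <- grid_cell_um(spec)
  cell_px <- cell_um / spec$pixel_size
  slots_per_field <- spec$grid_dim^2
  n_fields <- spec$replicates * spec$fields_per_replicate
  capacity <- n_fields * slots_per_field

  out <- vector("list", length(spec$arms))
  for (a in seq_along(spec$arms)) {
    arm <- spec$arms[[a]]
    n <- arm$n_organoids
    if (n > capacity) {
      stop("arm '", arm$treatment_label, "': cannot place ", n,
           " organoids without overlap in ", n_fields, " field(s) of ",
           slots_per_field, " grid cells (capacity ", capacity,
           "); increase fields/replicates or grid_dim")
    }
    set.seed(child_seed(spec$seed, a))
    d0 <- sample_law(arm$d0_diameter_law, n)
    d0 <- pmin(pmax(d0, 20), 0.45 * cell_um)
    g <- pmax(sample_law(arm$growth_pct_law, n), -95)
    d4 <- pmin(d0 * (1 + g / 100), 0.92 * cell_um)
    growth <- 100 * (d4 / d0 - 1)
    orr0 <- pmin(pmax(sample_law(arm$orr0_law, n), 0.01), 0.99)
    orr4 <- pmin(pmax(orr0 + sample_law(arm$delta_orr_law, n), 0.01), 0.99)
    present <- stats::runif(n) >= arm$dropout_rate
    # shape is a per-organoid property, shared across days
    ecc <- stats::runif(n, 0.75, 1)
    theta <- stats::runif(n, 0, pi)

    slot <- seq_len(n) - 1L           # fill fields sequentially, cell-major
    field_global <- slot %/% slots_per_field
    cell_idx <- slot %% slots_per_field
    replicate <- field_global %/% spec$fields_per_replicate + 1L
    field_index <- field_global %% spec$fields_per_replicate + 1L
    cell_row <- cell_idx %/% spec$grid_dim + 1L
    cell_col <- cell_idx %% spec$grid_dim + 1L

    # centre = cell centre + lateral jitter; day-4 adds small gel drift.
    # jitter bound keeps the whole mask inside its own cell.
    jit <- 0.03 * cell_px
    x0 <- (cell_row - 0.5) * cell_px + stats::runif(n, -jit, jit)
    y0 <- (cell_col - 0.5) * cell_px + stats::runif(n, -jit, jit)
    drift <- 5 / spec$pixel_size
    x4 <- x0 + stats::rnorm(n, 0, drift)
    y4 <- y0 + stats::rnorm(n, 0, drift)

    out[[a]] <- data.frame(
      organoid_id = sprintf("%s-%s-%04d", spec$line_id, arm$treatment_label,
                            seq_len(n)),
      line_id = spec$line_id,
      arm = arm$treatment_label,
      replicate = replicate,
      field_index = field_index,
      cell_row = cell_row,
      cell_col = cell_col,
      x0_px = x0, y0_px = y0, x4_px = x4, y4_px = y4,
      d0_um = d0, d4_um = ifelse(present, d4, NA_real_),
      growth_pct = ifelse(present, growth, NA_real_),
      orr0 = orr0, orr4 = ifelse(present, orr4, NA_real_),
      delta_orr = ifelse(present, orr4 - orr0, NA_real_),
      ecc = ecc, theta = theta,
      viability = arm$viability_factor,
      present_day4 = present,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate a CellTiter-Glo-style well luminescence readout
#'
#' ATP content scales with viable cell mass, modelled as proportional to the
#' summed cubed diameters of the organoids sharing a well, scaled by each
#' organoid's viability factor, with multiplicative Gaussian noise:
#' `c * sum(d_i^3 * viability_i) * (1 + eps)`, `eps ~ N(0, noise_cv)`.
#'
#' @param diameters_um Organoid diameters in the well (um).
#' @param viability Per-organoid viability factors (recycled).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param scale Proportionality constant `c` (arbitrary luminescence units).
#' @param noise_floor Additive floor returned for an empty well.
#' @return Luminescence in arbitrary units.
#' @export
simulate_well_luminescence <- function(diameters_um, viability = 1,
                                       noise_cv = 0, scale = 1,
                                       noise_floor = 0) {
  if (length(diameters_um) == 0) {
    return(noise_floor + abs(stats::rnorm(1, 0, noise_cv * max(noise_floor, 1))))
  }
  stopifnot(all(diameters_um > 0))
  base <- scale * sum(diameters_um^3 * viability)
  base * (1 + stats::rnorm(1, 0, noise_cv))
}

#' Simulate a clinical sum-of-longest-diameter (SLD) outcome
#'
#' Maps an organoid-level true effect size (mGlass's delta scale) to a
#' simulated pre/post-treatment SLD pair through a linear link on the percent
#' change scale: `pct_change = intercept + slope * effect + noise`. With the
#' default slope of -35% per effect-size unit, an effect of about 0.9 maps to
#' roughly the -31% SLD change seen for a moderately sensitive line, and
#' effects past the chemotherapy sensitivity cutoff map well below the -30%
#' RECIST partial-response boundary. The percent change is clamped to
#' [-100, 200].
#'
#' @param true_effect Effect size on the mGlass's delta scale.
#' @param sld_pre Pre-treatment SLD in mm (default 100).
#' @param intercept,slope Link parameters (percent, percent per effect unit).
#' @param noise_sd SD of Gaussian noise on the percent change.
#' @param seed Optional seed for reproducibility of the noise draw.
#' @return Named numeric vector `c(sld_pre=, sld_post=)` in mm.
#' @export
simulate_clinical_outcome <- function(true_effect, sld_pre = 100,
                                      intercept = 0, slope = -35,
                                      noise_sd = 0, seed = NULL) {
  stopifnot(sld_pre > 0)
  if (!is.null(seed)) set.seed(seed)
  pct <- intercept + slope * true_effect + stats::rnorm(1, 0, noise_sd)
  pct <- min(max(pct, -100), 200)
  c(sld_pre = sld_pre, sld_post = sld_pre * (1 + pct / 100))
}
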