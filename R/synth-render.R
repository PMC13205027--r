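#' Channel rendering parameters for the synthetic imager
#'
#' Intensity model of the three channels, in camera counts (16-bit range).
#' Brightfield (BF) shows each organoid as a dark-rimmed, slightly darkened
#' ellipse on a bright background. The NAD(P)H and FAD channels share a
#' radial profile concentrated toward the organoid rim; per-organoid channel
#' amplitudes are split so that the background-subtracted intensity ratio
#' reproduces the organoid's true ORR for any mask, since the profile cancels
#' in the ratio of mask means.
#'
#' @param bf_background,bf_interior,bf_rim BF levels (counts).
#' @param bf_noise_sd BF additive Gaussian noise SD (counts).
#' @param fluor_background Autofluorescence background level (counts), shared
#'   by the NAD(P)H and FAD channels.
#' @param fluor_amplitude Total fluorescence amplitude S of one organoid at
#'   the rim; NAD(P)H gets `S * orr`, FAD gets `S * (1 - orr)`.
#' @param fluor_noise_sd Additive Gaussian noise SD for both fluorescence
#'   channels (counts).
#' @param poisson If `TRUE`, add Poisson shot noise (counts drawn as
#'   `rpois(lambda = signal)`) before the Gaussian read noise.
#' @param rim_px Width of the dark BF rim, in pixels along the minor axis.
#' @param edge_decay_px Length scale of the inward exponential decay of the
#'   fluorescence profile (px); emulates the bright leading edge.
#' @param edge_base Floor of the fluorescence profile in the organoid core,
#'   as a fraction of the rim amplitude.
#' @return A list of class `"channel_params"`.
#' @export
channel_params <- function(bf_background = 3000, bf_interior = 2200,
                           bf_rim = 1000, bf_noise_sd = 50,
                           fluor_background = 400, fluor_amplitude = 2000,
                           fluor_noise_sd = 20, poisson = FALSE,
                           rim_px = 3, edge_decay_px = 15, edge_base = 0.35) {
  structure(as.list(environment()), class = "channel_params")
}

#' Render one multi-channel field at one imaging day
#'
#' Draws every organoid assigned to one (arm, replicate, field) triple as an
#' ellipse whose major axis equals its true longest diameter, then adds
#' channel background and noise. At Day 4, organoids flagged absent
#' (`present_day4 = FALSE`) are not drawn.
#'
#' @param organoids Rows of a [generate_cohort()] table belonging to a single
#'   arm, replicate and field.
#' @param day Imaging day, 0 or 4.
#' @param spec The [cohort_spec()] the cohort was generated from (supplies
#'   field size and pixel size).
#' @param params A [channel_params()] list.
#' @param seed Optional seed for the noise draw (the pipeline derives one per
#'   field and day from the master seed).
#' @param return_truth If `TRUE`, attach the ground-truth label image
#'   (`truth_labels`, integer matrix; value k = k-th row of `organoids`
#'   drawn) for segmentation fidelity checks.
#' @return An object of class `"field_image"`: list with integer matrices
#'   `bf`, `nadph`, `fad` (counts, 16-bit range), `pixel_size`, `day`,
#'   `field_index`, `replicate`, `arm`, `line_id`, and `clipped_ids`
#'   (organoid ids whose ellipse extended beyond the field and was clipped).
#' @export
render_field <- function(organoids, day, spec, params = channel_params(),
                         seed = NULL, return_truth = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"), day %in% c(0, 4),
            inherits(params, "channel_params"))
  if (nrow(organoids) > 0) {
    key <- unique(organoids[c("arm", "replicate", "field_index")])
    if (nrow(key) != 1) {
      stop("organoids must all belong to one (arm, replicate, field) triple")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  nr <- spec$field_size_px[1]
  nc <- spec$field_size_px[2]
  bf <- matrix(params$bf_background, nr, nc)
  nadph <- matrix(params$fluor_background, nr, nc)
  fad <- matrix(params$fluor_background, nr, nc)
  truth <- if (return_truth) matrix(0L, nr, nc) else NULL
  clipped <- character(0)

  draw <- organoids
  if (day == 4 && nrow(draw) > 0) draw <- draw[draw$present_day4, , drop = FALSE]

  for (k in seq_len(nrow(draw))) {
    o <- draw[k, ]
    cx <- if (day == 0) o$x0_px else o$x4_px
    cy <- if (day == 0) o$y0_px else o$y4_px
    d_px <- (if (day == 0) o$d0_um else o$d4_um) / spec$pixel_size
    a <- d_px / 2
    b <- o$ecc * a
    ext <- a + 1
    xr <- floor(cx - ext):ceiling(cx + ext)
    yr <- floor(cy - ext):ceiling(cy + ext)
    if (min(xr) < 1 || max(xr) > nr || min(yr) < 1 || max(yr) > nc) {
      clipped <- c(clipped, o$organoid_id)
      xr <- xr[xr >= 1 & xr <= nr]
      yr <- yr[yr >= 1 & yr <= nc]
    }
    if (!length(xr) || !length(yr)) next
    dx <- xr - cx
    dy <- yr - cy
    ct <- cos(o$theta); st <- sin(o$theta)
    u <- outer(dx * ct, dy * st, "+")            # rotated coords
    v <- outer(-dx * st, dy * ct, "+")
    ru <- sqrt((u / a)^2 + (v / b)^2)            # normalised ellipse radius
    inside <- ru <= 1
    if (!any(inside)) {
      # sub-pixel remnant: an object below sampling resolution still darkens
      # the pixel it sits in, so draw (at least) the nearest pixel centre
      inside <- ru == min(ru)
    }
    rim <- inside & (ru >= 1 - params$rim_px / b)

    sub_bf <- bf[xr, yr]
    sub_bf[inside] <- params$bf_interior
    sub_bf[rim] <- params$bf_rim
    bf[xr, yr] <- sub_bf

    # shared radial profile -> ratio of mask means equals true ORR exactly
    w <- params$edge_base +
      (1 - params$edge_base) * exp(-pmax(1 - ru, 0) * b / params$edge_decay_px)
    orr <- if (day == 0) o$orr0 else o$orr4
    sub <- nadph[xr, yr]
    sub[inside] <- sub[inside] + params$fluor_amplitude * orr * w[inside]
    nadph[xr, yr] <- sub
    sub <- fad[xr, yr]
    sub[inside] <- sub[inside] + params$fluor_amplitude * (1 - orr) * w[inside]
    fad[xr, yr] <- sub

    if (return_truth) {
      subt <- truth[xr, yr]
      subt[inside] <- k
      truth[xr, yr] <- subt
    }
  }

  quantize <- function(x, noise_sd) {
    dm <- dim(x)
    if (params$poisson) x <- stats::rpois(length(x), x)
    if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
    v <- as.integer(round(x))
    v[v < 0L] <- 0L
    v[v > 65535L] <- 65535L
    matrix(v, dm[1], dm[2])
  }
  out <- structure(list(
    bf = quantize(bf, params$bf_noise_sd),
    nadph = quantize(nadph, params$fluor_noise_sd),
    fad = quantize(fad, params$fluor_noise_sd),
    pixel_size = spec$pixel_size,
    day = day,
    field_index = if (nrow(organoids)) organoids$field_index[1] else NA_integer_,
    replicate = if (nrow(organoids)) organoids$replicate[1] else NA_integer_,
    arm = if (nrow(organoids)) organoids$arm[1] else NA_character_,
    line_id = if (nrow(organoids)) organoids$line_id[1] else NA_character_,
    clipped_ids = clipped
  ), class = "field_image")
  if (return_truth) {
    out$truth_labels <- truth
    out$truth_ids <- draw$organoid_id
  }
  out
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image %s/%s rep %s field %s day %s: %d x %d px @ %.3f um/px>\n",
              x$line_id, x$arm, x$replicate, x$field_index, x$day,
              nrow(x$bf), ncol(x$bf), x$pixel_size))
  invisible(x)
}
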