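#' Segmentation parameters
#'
#' @param gblur_sigma Gaussian smoothing sigma (px) applied to the inverted
#'   brightfield before thresholding.
#' @param min_area_um2 Minimum object area (um^2); smaller components are
#'   discarded. Default 2000 um^2, about a 50 um disk.
#' @param split_touching Split touching objects with a marker-based watershed
#'   on the distance transform.
#' @param watershed_tolerance Minimum distance-map depth (px) between two
#'   objects for the watershed to split them.
#' @param dilate_bg_px Labels are dilated by this radius (px) before taking
#'   the complement as the background region, to keep organoid halos out of
#'   the background estimate.
#' @param min_contrast_mad Blank-field guard: segmentation returns zero labels
#'   unless the foreground/background class means are separated by at least
#'   this multiple of the background median absolute deviation.
#' @return A list of class `"seg_params"`.
#' @export
seg_params <- function(gblur_sigma = 1.5, min_area_um2 = 2000,
                       split_touching = TRUE, watershed_tolerance = 2,
                       dilate_bg_px = 10, min_contrast_mad = 6) {
  structure(as.list(environment()), class = "seg_params")
}

# Separable Gaussian smoothing with edge replication. stats::filter runs the
# convolution in C along matrix columns, so two padded passes cover 2-D.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- ceiling(3 * sigma)
  g <- stats::dnorm(-k:k, 0, sigma)
  g <- g / sum(g)
  pass <- function(m) {
    padded <- rbind(m[rep(1, k), , drop = FALSE], m,
                    m[rep(nrow(m), k), , drop = FALSE])
    out <- stats::filter(padded, g, sides = 2)
    matrix(out[(k + 1):(k + nrow(m)), ], nrow(m), ncol(m))
  }
  t(pass(t(pass(x))))
}

#' Segment organoids in a brightfield field
#'
#' Classical segmenter for the dark-rimmed organoid phantoms: the brightfield
#' channel is inverted and rescaled, smoothed, thresholded with Otsu's
#' method, hole-filled, filtered by minimum area, and touching objects are
#' split with a marker-based watershed on the distance transform. A blank
#' field (no real intensity structure) yields zero labels rather than an
#' error. The segmenter is intensity-scale invariant: multiplying the
#' brightfield by a positive constant leaves the labels unchanged.
#'
#' @param field A [render_field()] `field_image` (or any list with a `bf`
#'   matrix and `pixel_size`).
#' @param params A [seg_params()] list.
#' @return A list of class `"segmentation_result"`: `label_image` (integer
#'   matrix, 0 = background, labels contiguous 1..K), `n_labels`,
#'   `background_mask` (logical; complement of the dilated labels), and
#'   `stats` (data.frame: label, area_px, area_um2, centroid x/y in px).
#' @export
segment_organoids <- function(field, params = seg_params()) {
  stopifnot(inherits(params, "seg_params"))
  bf <- field$bf
  px <- field$pixel_size
  empty <- function() {
    structure(list(
      label_image = matrix(0L, nrow(bf), ncol(bf)),
      n_labels = 0L,
      background_mask = matrix(TRUE, nrow(bf), ncol(bf)),
      stats = data.frame(label = integer(0), area_px = integer(0),
                         area_um2 = numeric(0), x_px = numeric(0),
                         y_px = numeric(0)),
      pixel_size = px
    ), class = "segmentation_result")
  }
  rng <- range(bf)
  if (diff(rng) == 0) return(empty())

  inv <- (rng[2] - bf) / diff(rng)       # objects darker than background
  # Otsu level and blank-field guard are estimated on a smoothed, 2x
  # downsampled copy: the level only has to fall between the intensity
  # classes, so it is insensitive to the sampling
  est <- inv[seq(1, nrow(inv), by = 2), seq(1, ncol(inv), by = 2)]
  sm <- gauss_blur(est, params$gblur_sigma / 2)
  thr <- EBImage::otsu(EBImage::Image(sm), range = range(sm))
  fg_est <- sm > thr
  if (mean(fg_est) > 0.4 || !any(fg_est)) return(empty())
  # blank-field guard: demand real contrast between the Otsu classes
  bg_mad <- stats::mad(sm[!fg_est])
  sep <- mean(sm[fg_est]) - mean(sm[!fg_est])
  if (bg_mad > 0 && sep < params$min_contrast_mad * bg_mad) return(empty())

  # the smoothed image stabilises the Otsu level; the mask itself is taken
  # from the unsmoothed image at that level, so the smoothing halo does not
  # dilate the masks (~1 px bias otherwise) and sub-resolution Day-4
  # remnants, which smoothing would erase, stay detectable
  fg <- inv > thr
  if (!any(fg)) return(empty())
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::bwlabel(fg)
  min_area_px <- params$min_area_um2 / px^2
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  if (!length(keep)) return(empty())
  fg <- matrix(lab %in% keep, nrow(lab), ncol(lab))

  if (params$split_touching) {
    # watershed runs per connected component on its padded bounding box:
    # components are independent, and the crops make the distance transform
    # cost proportional to object area, not field area
    comp <- EBImage::bwlabel(fg)
    cidx <- which(comp > 0, arr.ind = TRUE)
    groups <- split(seq_len(nrow(cidx)), comp[comp > 0])
    lab <- matrix(0L, nrow(fg), ncol(fg))
    nxt <- 0L
    for (g in groups) {
      gp <- cidx[g, , drop = FALSE]
      x0 <- max(min(gp[, 1]) - 1L, 1L); x1 <- min(max(gp[, 1]) + 1L, nrow(fg))
      y0 <- max(min(gp[, 2]) - 1L, 1L); y1 <- min(max(gp[, 2]) + 1L, ncol(fg))
      crop <- comp[x0:x1, y0:y1] == comp[gp[1, 1], gp[1, 2]]
      ws <- EBImage::watershed(EBImage::distmap(crop),
                               tolerance = params$watershed_tolerance, ext = 1)
      ws <- matrix(as.integer(ws), nrow(ws), ncol(ws))
      sub_areas <- tabulate(ws[ws > 0])
      sub <- lab[x0:x1, y0:y1]
      for (s in which(sub_areas >= min_area_px)) {
        nxt <- nxt + 1L
        sub[ws == s] <- nxt
      }
      lab[x0:x1, y0:y1] <- sub
    }
    if (nxt == 0L) return(empty())
  } else {
    lab <- EBImage::bwlabel(fg)
  }

  # relabel contiguously, ordered by first (column-major) pixel: deterministic
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nz <- lab > 0
  lv <- lab[nz]
  old <- unique(lv)                      # order of first appearance
  relab <- integer(max(old))
  relab[old] <- seq_along(old)
  lv <- relab[lv]
  lab[nz] <- lv

  idx <- which(nz, arr.ind = TRUE)
  area_px <- tabulate(lv, nbins = length(old))
  xs <- rowsum(as.numeric(idx[, 1]), lv)[, 1] / area_px
  ys <- rowsum(as.numeric(idx[, 2]), lv)[, 1] / area_px

  brush_r <- params$dilate_bg_px
  dil <- EBImage::dilate(lab > 0, EBImage::makeBrush(2 * brush_r + 1, "disc"))
  structure(list(
    label_image = lab,
    n_labels = length(old),
    background_mask = !(dil > 0),
    stats = data.frame(label = seq_along(old), area_px = area_px,
                       area_um2 = area_px * px^2, x_px = xs, y_px = ys),
    pixel_size = px
  ), class = "segmentation_result")
}

#' Leading-edge mask of one labelled organoid
#'
#' The leading edge is the outer band of the organoid mask: pixels whose
#' distance-transform value (distance to the nearest background pixel) is at
#' most `width_px`. An object thinner than twice the band width yields its
#' full mask.
#'
#' @param label_image Integer label matrix (0 = background).
#' @param label The label to extract.
#' @param width_px Band width in pixels (default 20, the validated leading
#'   edge width at 1.634 um/px, about 33 um).
#' @return Logical matrix of the same shape as `label_image`.
#' @export
leading_edge_mask <- function(label_image, label, width_px = 20) {
  mask <- label_image == label
  if (!any(mask)) stop("label ", label, " not present in label image")
  idx <- which(mask, arr.ind = TRUE)
  # crop with a 1-px pad so the distance transform sees the object boundary
  x0 <- max(min(idx[, 1]) - 1L, 1L); x1 <- min(max(idx[, 1]) + 1L, nrow(mask))
  y0 <- max(min(idx[, 2]) - 1L, 1L); y1 <- min(max(idx[, 2]) + 1L, ncol(mask))
  crop <- mask[x0:x1, y0:y1]
  dm <- EBImage::distmap(crop)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[x0:x1, y0:y1] <- crop & dm <= width_px
  out
}

#' Background-normalize an intensity channel
#'
#' Estimates the field background as the median intensity over the background
#' mask and removes it, to correct day-to-day variation of the widefield
#' system. Subtraction (default) returns `pmax(channel - background, 0)`;
#' division returns `channel / background`.
#'
#' @param channel Intensity matrix.
#' @param background_mask Logical matrix marking background pixels; at least
#'   100 pixels are required for a stable median.
#' @param method `"subtract"` (default) or `"divide"`.
#' @return Normalized matrix with attribute `background_level` (the estimated
#'   background, in input units).
#' @export
background_normalize <- function(channel, background_mask,
                                 method = c("subtract", "divide")) {
  method <- match.arg(method)
  stopifnot(all(dim(channel) == dim(background_mask)))
  n_bg <- sum(background_mask)
  if (n_bg < 100) {
    stop("background region too small (", n_bg, " px); use a larger field ",
         "or a lower min_area so more of the field is classified background")
  }
  v <- channel[background_mask]
  # a regular subsample keeps the median estimate deterministic and cheap;
  # its SE at 2e4 pixels is well below one count for any realistic noise
  if (length(v) > 20000) v <- v[seq(1, length(v), length.out = 20000)]
  bg <- stats::median(v)
  out <- switch(method,
    subtract = pmax(channel - bg, 0),
    divide = channel / bg
  )
  attr(out, "background_level") <- bg
  out
}
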