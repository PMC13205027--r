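#' Longest (maximum Feret) diameter of a mask
#'
#' The longest diameter is the greatest distance between any two boundary
#' pixel centres of the object, plus one pixel to account for pixel extent
#' (so a single pixel has diameter one pixel, not zero), converted to
#' micrometres. This mirrors a manual longest-diameter line measurement on a
#' brightfield image.
#'
#' @param mask Logical (or 0/1) matrix containing one object.
#' @param pixel_size Pixel size in um/px.
#' @return Diameter in micrometres.
#' @export
longest_diameter <- function(mask, pixel_size) {
  stopifnot(pixel_size > 0)
  pts <- which(mask > 0, arr.ind = TRUE)
  if (nrow(pts) == 0) stop("empty mask: longest diameter undefined")
  feret_px(pts) * pixel_size
}

# max pairwise distance between pixel centres, + 1 px pixel-extent correction
feret_px <- function(pts) {
  if (nrow(pts) == 1) return(1)
  if (nrow(pts) > 3) {
    hull <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[hull, , drop = FALSE]
  }
  max(stats::dist(pts)) + 1
}

#' Relative change in diameter
#'
#' `100 * (d4 - d0) / d0`, the per-organoid percent growth between the
#' pre-treatment (Day 0) and post-treatment (Day 4) images.
#'
#' @param d0_um,d4_um Longest diameters on Day 0 and Day 4 (same units).
#' @return Percent change (vectorized).
#' @export
relative_change <- function(d0_um, d4_um) {
  if (any(d0_um <= 0, na.rm = TRUE)) stop("relative_change: d0 must be > 0")
  100 * (d4_um - d0_um) / d0_um
}

#' Pair organoid detections across imaging days
#'
#' Greedy nearest-centroid matching within each (replicate, field) pair:
#' candidate pairs with centroid shift at most `max_shift_um` are accepted in
#' order of increasing distance (ties broken by detection order), each
#' detection used at most once. Organoids are embedded in gel on gridded
#' dishes, so true shifts are small; the default acceptance radius is 150 um.
#'
#' @param day0,day4 Detection data.frames, one row per detection, with
#'   columns `replicate`, `field_index`, `label`, `x_um`, `y_um` (centroids
#'   in micrometres) plus any measurement columns to carry through.
#' @param max_shift_um Maximum accepted centroid shift (um).
#' @return A data.frame with one row per Day-0 detection: all `day0` columns
#'   suffixed `_d0`, the matched `day4` columns suffixed `_d4` (NA when
#'   unmatched), `paired` flag and centroid `shift_um`. Unmatched Day-4
#'   detections (new objects) are attached as attribute `unmatched_day4`.
#' @export
pair_organoids <- function(day0, day4, max_shift_um = 150) {
  req <- c("replicate", "field_index", "label", "x_um", "y_um")
  stopifnot(all(req %in% names(day0)), all(req %in% names(day4)))
  f0 <- unique(day0[c("replicate", "field_index")])
  f4 <- unique(day4[c("replicate", "field_index")])
  key <- function(d) paste(d$replicate, d$field_index)
  if (!setequal(key(f0), key(f4))) {
    stop("day0 and day4 detections cover different (replicate, field) sets")
  }

  match4 <- rep(NA_integer_, nrow(day0))
  used4 <- rep(FALSE, nrow(day4))
  shift <- rep(NA_real_, nrow(day0))
  for (fk in unique(key(f0))) {
    i0 <- which(key(day0) == fk)
    i4 <- which(key(day4) == fk)
    if (!length(i0) || !length(i4)) next
    dmat <- outer(day0$x_um[i0], day4$x_um[i4], "-")^2 +
      outer(day0$y_um[i0], day4$y_um[i4], "-")^2
    dmat <- sqrt(dmat)
    cand <- which(dmat <= max_shift_um, arr.ind = TRUE)
    if (!nrow(cand)) next
    ord <- order(dmat[cand], cand[, 1], cand[, 2])
    for (ci in ord) {
      a <- cand[ci, 1]; b <- cand[ci, 2]
      if (!is.na(match4[i0[a]]) || used4[i4[b]]) next
      match4[i0[a]] <- i4[b]
      used4[i4[b]] <- TRUE
      shift[i0[a]] <- dmat[a, b]
    }
  }

  names(day0) <- paste0(names(day0), "_d0")
  d4cols <- day4[ifelse(is.na(match4), NA_integer_, match4), , drop = FALSE]
  names(d4cols) <- paste0(names(d4cols), "_d4")
  rownames(d4cols) <- NULL
  out <- cbind(day0, d4cols, paired = !is.na(match4), shift_um = shift)
  attr(out, "unmatched_day4") <- day4[!used4, , drop = FALSE]
  out
}
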