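#' Measure all organoids in one field
#'
#' Runs segmentation (unless a result is supplied), background-normalizes the
#' two autofluorescence channels against the field's background region, and
#' for every labelled organoid measures the longest (max Feret) diameter from
#' the label mask, the leading-edge mean intensities of both channels, and
#' the optical redox ratio.
#'
#' @param field A [render_field()] `field_image`.
#' @param seg Optional precomputed [segment_organoids()] result.
#' @param edge_width_px Leading-edge band width in pixels.
#' @param params [seg_params()] used when `seg` is not supplied.
#' @param normalize_method Passed to [background_normalize()].
#' @return data.frame with one row per detected organoid: `replicate`,
#'   `field_index`, `day`, `label`, centroid `x_um`, `y_um`, `diameter_um`,
#'   `i_nadph`, `i_fad`, `orr`. Attribute `background_levels` records the
#'   estimated per-channel backgrounds.
#' @export
measure_field <- function(field, seg = NULL, edge_width_px = 20,
                          params = seg_params(),
                          normalize_method = "subtract") {
  if (is.null(seg)) seg <- segment_organoids(field, params)
  px <- field$pixel_size
  k <- seg$n_labels
  base <- data.frame(
    replicate = rep(field$replicate, k), field_index = rep(field$field_index, k),
    day = rep(field$day, k), label = integer(k),
    x_um = numeric(k), y_um = numeric(k), diameter_um = numeric(k),
    i_nadph = numeric(k), i_fad = numeric(k), orr = numeric(k)
  )
  if (k == 0) return(base)

  nadph <- background_normalize(field$nadph, seg$background_mask,
                                normalize_method)
  fad <- background_normalize(field$fad, seg$background_mask,
                              normalize_method)
  lab <- seg$label_image
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  ord <- order(lv)
  idx <- idx[ord, , drop = FALSE]
  lv <- lv[ord]
  splits <- split(seq_along(lv), lv)

  for (li in seq_len(k)) {
    pts <- idx[splits[[as.character(li)]], , drop = FALSE]
    # crop to the label's bounding box (1-px pad) for the distance transform
    x0 <- max(min(pts[, 1]) - 1L, 1L); x1 <- min(max(pts[, 1]) + 1L, nrow(lab))
    y0 <- max(min(pts[, 2]) - 1L, 1L); y1 <- min(max(pts[, 2]) + 1L, ncol(lab))
    crop <- lab[x0:x1, y0:y1] == li
    dm <- EBImage::distmap(crop)
    edge <- crop & dm <= edge_width_px
    n_sub <- nadph[x0:x1, y0:y1]
    f_sub <- fad[x0:x1, y0:y1]
    base$label[li] <- li
    base$x_um[li] <- seg$stats$x_px[li] * px
    base$y_um[li] <- seg$stats$y_px[li] * px
    base$diameter_um[li] <- feret_px(pts) * px
    base$i_nadph[li] <- mean(n_sub[edge])
    base$i_fad[li] <- mean(f_sub[edge])
    base$orr[li] <- organoid_orr(n_sub, f_sub, edge)
  }
  attr(base, "background_levels") <- c(
    nadph = attr(nadph, "background_level"),
    fad = attr(fad, "background_level")
  )
  base
}
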