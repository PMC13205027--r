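#' Optical redox ratio of one organoid
#'
#' ORR = I_NADPH / (I_NADPH + I_FAD), where I is the mean background-normalized
#' intensity over the organoid's leading-edge mask. The ratio of mask means
#' (rather than the mean of per-pixel ratios) is used: it is robust to
#' individual zero-intensity pixels and is the conventional intensity
#' statistic for the measurement.
#'
#' @param nadph_norm,fad_norm Background-normalized channel matrices.
#' @param edge_mask Logical matrix selecting the leading-edge pixels.
#' @return ORR in \[0, 1\], or `NA` (undefined-ORR flag) when both channel
#'   means are zero; such records are excluded downstream with a logged
#'   count rather than raising an error.
#' @export
organoid_orr <- function(nadph_norm, fad_norm, edge_mask) {
  if (!any(edge_mask)) stop("organoid_orr: empty edge mask")
  mn <- mean(nadph_norm[edge_mask])
  mf <- mean(fad_norm[edge_mask])
  if (mn < 0 || mf < 0) stop("organoid_orr: negative channel mean; ",
                             "channels must be background-normalized")
  if (mn + mf == 0) return(NA_real_)
  mn / (mn + mf)
}

#' Per-organoid change in optical redox ratio
#'
#' The simple paired difference `orr_day4 - orr_day0`, so that a metabolic
#' decrease after treatment gives a negative value. Values lie in \[-1, 1\].
#'
#' @param orr_day0,orr_day4 ORR of the same organoid on each day (vectorized).
#' @return ΔORR.
#' @export
delta_orr <- function(orr_day0, orr_day4) {
  bad <- !is.na(orr_day0) & !is.na(orr_day4) &
    (orr_day0 < 0 | orr_day0 > 1 | orr_day4 < 0 | orr_day4 > 1)
  if (any(bad)) stop("delta_orr: ORR values must lie in [0, 1]")
  orr_day4 - orr_day0
}
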