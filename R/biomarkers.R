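# Per-image morphology biomarkers from the filtered segment set.

#' Tortuosity (arc-chord ratio) of edge segments
#'
#' The ratio of traced path length to end-to-end chord, `c / d`. Straight
#' segments give 1; cycles (`d = 0`) are undefined and return `NA` (they are
#' skipped by the aggregator).
#'
#' @param c_um path length(s) in micrometres, or a `skeleton_graph`.
#' @param d_um chord length(s) in micrometres (ignored if `c_um` is a graph).
#' @return Numeric vector of tortuosities (>= 1 for traced skeleton paths).
#' @export
tortuosity <- function(c_um, d_um = NULL) {
  if (inherits(c_um, "skeleton_graph")) {
    d_um <- c_um$segments$d_um
    c_um <- c_um$segments$c_um
  }
  ifelse(d_um > 0, c_um / d_um, NA_real_)
}

#' Orientation angle of edge segments
#'
#' The angle of the chord between the two segment ends, `atan2(h, w)` with
#' `h` the vertical and `w` the horizontal chord component, folded into
#' `[0, pi)` because segments are undirected. Cycles return `NA`.
#'
#' @param h_um signed vertical chord component(s), or a `skeleton_graph`.
#' @param w_um signed horizontal chord component(s).
#' @return Angles in radians in `[0, pi)`.
#' @export
orientation_angle <- function(h_um, w_um = NULL) {
  if (inherits(h_um, "skeleton_graph")) {
    segs <- h_um$segments
    return(ifelse(segs$d_um > 0, fold_angle(atan2(segs$h_um, segs$w_um)), NA_real_))
  }
  fold_angle(atan2(h_um, w_um))
}

# population standard deviation (n divisor)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# circular mean of axial data (angles modulo pi), via angle doubling
axial_mean <- function(theta) {
  fold_angle(atan2(mean(sin(2 * theta)), mean(cos(2 * theta))) / 2)
}

#' Compute the per-image biomarker set
#'
#' From a filtered [skeleton_graph()]: median tortuosity over segments with a
#' positive chord; segment count and count per square millimetre; median edge
#' segment distance (the traced path length `c_um`; the chord median is also
#' reported); population standard deviation and interquartile range (linear
#' percentile interpolation) of the folded orientation angles.
#'
#' The plain fold to `[0, pi)` is not wrap-invariant: a bundle straddling the
#' 0 / pi seam inflates the dispersion statistics. `recenter_axial = TRUE`
#' rotates angles by the axial (doubled-angle) circular mean before measuring
#' dispersion, making them seam-independent; it is off by default.
#'
#' @param G a filtered `skeleton_graph`.
#' @param group treatment-group label attached to the output row.
#' @param recenter_axial logical; recentre angles before SD/IQR.
#' @return One-row data frame of class `biomarker_set`.
#' @export
compute_biomarkers <- function(G, group = NA_character_, recenter_axial = FALSE) {
  segs <- G$segments
  usable <- which(segs$d_um > 0)
  n_seg <- nrow(segs)
  out <- data.frame(
    group = as.character(group),
    n_segments = n_seg,
    n_segments_per_mm2 = n_seg / G$area_mm2,
    median_tortuosity = NA_real_,
    median_segment_distance_um = NA_real_,
    median_chord_um = NA_real_,
    sd_orientation_rad = NA_real_,
    iqr_orientation_rad = NA_real_,
    stringsAsFactors = FALSE)
  if (length(usable) == 0L) {
    out$n_segments_per_mm2 <- if (n_seg == 0L) NA_real_ else out$n_segments_per_mm2
    class(out) <- c("biomarker_set", "data.frame")
    return(out)
  }
  tau <- segs$c_um[usable] / segs$d_um[usable]
  theta <- fold_angle(atan2(segs$h_um[usable], segs$w_um[usable]))
  if (recenter_axial) {
    theta <- fold_angle(theta - axial_mean(theta) + pi / 2)
  }
  q <- stats::quantile(theta, c(0.25, 0.75), type = 7, names = FALSE)
  out$median_tortuosity <- stats::median(tau)
  out$median_segment_distance_um <- stats::median(segs$c_um)
  out$median_chord_um <- stats::median(segs$d_um)
  out$sd_orientation_rad <- sd_pop(theta)
  out$iqr_orientation_rad <- q[2] - q[1]
  class(out) <- c("biomarker_set", "data.frame")
  out
}
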