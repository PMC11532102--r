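# Edge-probability maps, orientation estimation, and non-maximum suppression.

# central differences inside, one-sided at the borders
.gradient_rc <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  gr <- (shift_mat(g, -1, 0) - shift_mat(g, 1, 0)) / 2
  gc <- (shift_mat(g, 0, -1) - shift_mat(g, 0, 1)) / 2
  gr[1, ] <- g[2, ] - g[1, ]; gr[nr, ] <- g[nr, ] - g[nr - 1, ]
  gc[, 1] <- g[, 2] - g[, 1]; gc[, nc] <- g[, nc] - g[, nc - 1]
  list(gr = gr, gc = gc)
}

#' Edge probability map
#'
#' Per-pixel probability in `[0, 1]` that the pixel lies on a fiber edge,
#' together with the pixel calibration.
#'
#' @param prob numeric matrix with values in `[0, 1]`.
#' @param pixel_size_um calibration in micrometres per pixel.
#' @return An object of class `edge_prob_map`.
#' @export
edge_prob_map <- function(prob, pixel_size_um) {
  if (!is.matrix(prob)) stop("prob must be a matrix")
  rng <- range(prob, finite = TRUE)
  if (!all(is.finite(prob))) stop("probability map contains non-finite values")
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) stop("probabilities must lie in [0, 1]")
  prob[prob < 0] <- 0
  prob[prob > 1] <- 1
  if (pixel_size_um <= 0) stop("calibration error: pixel_size_um must be > 0")
  structure(list(prob = prob, pixel_size_um = as.numeric(pixel_size_um)),
            class = "edge_prob_map")
}

#' @export
print.edge_prob_map <- function(x, ...) {
  cat(sprintf("<edge_prob_map> %d x %d px, %.4g um/px, support %d px\n",
              nrow(x$prob), ncol(x$prob), x$pixel_size_um, sum(x$prob > 0)))
  invisible(x)
}

#' Load an externally produced edge-probability map
#'
#' Reads a grayscale image and rescales it by the format's full-scale value
#' (255 for 8-bit). Maps exported with white background / dark edges should be
#' loaded with `invert = TRUE`, which stores `1 - value`.
#'
#' @param path grayscale image file (PNG/TIFF/JPEG).
#' @param invert logical; if `TRUE` the loaded values are complemented.
#' @param pixel_size_um calibration in micrometres per pixel.
#' @return An [edge_prob_map()].
#' @export
load_probability_map <- function(path, invert = FALSE, pixel_size_um) {
  img <- read_image(path, pixel_size_um)
  if (length(dim(img$pixels)) != 2L) {
    stop("probability maps must be single-channel grayscale")
  }
  maxv <- attr(img, "max_value") %||% max(1, max(img$pixels))
  p <- img$pixels / maxv
  if (isTRUE(invert)) p <- 1 - p
  edge_prob_map(p, pixel_size_um)
}

#' Gradient-magnitude edge probability (weight-free backend)
#'
#' Gaussian-smoothed central-difference gradient magnitude, rescaled so its
#' maximum is 1. A constant image yields an all-zero map. This classical
#' backend serves when no pretrained edge detector output is available.
#'
#' @param img single-plane [calibrated_image()] (merge channels first).
#' @param smooth_sigma_px Gaussian smoothing scale in pixels.
#' @return An [edge_prob_map()].
#' @export
gradient_edge_probability <- function(img, smooth_sigma_px = 2) {
  px <- img$pixels
  if (length(dim(px)) != 2L) stop("merge channels before edge detection")
  if (!all(is.finite(px))) stop("image contains non-finite pixels")
  g <- gaussian_blur(px, smooth_sigma_px)
  gg <- .gradient_rc(g)
  mag <- sqrt(gg$gr^2 + gg$gc^2)
  mx <- max(mag)
  if (mx > 0) mag <- mag / mx
  edge_prob_map(mag, img$pixel_size_um)
}

#' Reinterpret a ridge-like image as an edge-probability surface
#'
#' Rescales intensities to `[0, 1]` by the image maximum (channel-max merged
#' first if needed). Appropriate when bright curvilinear ridges *are* the
#' structures to trace, e.g. synthetic fiber scenes or detector outputs saved
#' as plain images.
#'
#' @param img a [calibrated_image()].
#' @return An [edge_prob_map()].
#' @export
intensity_probability <- function(img) {
  img <- merge_channels(img)
  px <- img$pixels
  px <- px - min(px)
  mx <- max(px)
  if (mx > 0) px <- px / mx
  edge_prob_map(px, img$pixel_size_um)
}

#' Orientation field
#'
#' Per-pixel edge-tangent angle in `[0, pi)`: the direction perpendicular to
#' the gradient of the smoothed probability map. Constant regions get angle 0
#' by convention.
#'
#' @param P an [edge_prob_map()].
#' @param smooth_sigma_px smoothing scale for the gradient, in pixels.
#' @return An object of class `orientation_field` (list with matrix `theta`).
#' @export
estimate_orientation <- function(P, smooth_sigma_px = 2) {
  g <- gaussian_blur(P$prob, smooth_sigma_px)
  gg <- .gradient_rc(g)
  mag <- sqrt(gg$gr^2 + gg$gc^2)
  theta <- fold_angle(atan2(gg$gr, gg$gc) + pi / 2)
  theta[mag <= 1e-12] <- 0
  structure(list(theta = theta), class = "orientation_field")
}

#' Non-maximum suppression along the edge normal
#'
#' A pixel survives iff its probability (times a small plateau tolerance) is at
#' least the bilinearly interpolated probability at one pixel on either side
#' along the normal direction (perpendicular to the local tangent). Border
#' pixels compare only against in-bounds samples. Surviving pixels keep their
#' probability; others are set to 0.
#'
#' @param P an [edge_prob_map()].
#' @param O matching [estimate_orientation()] field.
#' @param tolerance multiplicative tie tolerance, >= 1 (default 1.01 retains
#'   plateau ties).
#' @return A thin map of class `thin_edge_map` (same fields as `edge_prob_map`).
#' @export
nonmax_suppress <- function(P, O, tolerance = 1.01) {
  prob <- P$prob
  theta <- O$theta
  if (!all(dim(prob) == dim(theta))) stop("probability map and orientation field shapes differ")
  if (tolerance < 1) stop("tolerance must be >= 1")
  nr <- nrow(prob); nc <- ncol(prob)
  rr <- rep(seq_len(nr), times = nc)
  cc <- rep(seq_len(nc), each = nr)
  # tangent (dc, dr) = (cos theta, sin theta); normal is (-sin theta, cos theta)
  ndr <- as.vector(cos(theta))
  ndc <- -as.vector(sin(theta))
  v1 <- bilinear_sample(prob, rr + ndr, cc + ndc)
  v2 <- bilinear_sample(prob, rr - ndr, cc - ndc)
  pv <- as.vector(prob)
  keep <- (is.na(v1) | pv * tolerance >= v1) & (is.na(v2) | pv * tolerance >= v2)
  out <- matrix(pv * keep, nr, nc)
  structure(list(prob = out, pixel_size_um = P$pixel_size_um),
            class = c("thin_edge_map", "edge_prob_map"))
}
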