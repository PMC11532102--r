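# Calibrated synthetic fiber scenes with analytic ground truth.

#' Specification of a synthetic fiber scene
#'
#' Parameters controlling a rendered bundle of bright curvilinear fibers on a
#' dark background: parallelism (uniform orientation jitter about a base
#' angle), waviness (sinusoidal centerline perturbation), split/branch events,
#' fiber length, Gaussian cross-section width, background noise and dark
#' elliptical "shadow" occluders. Rendering is deterministic given `seed`.
#'
#' @param image_size_px integer (rows, cols) of the rendered frame.
#' @param pixel_size_um calibration in micrometres per pixel (> 0).
#' @param n_fibers number of fibers.
#' @param base_angle_rad mean fiber orientation (chord angle, radians).
#' @param angle_jitter_rad half-width of the uniform per-fiber deviation.
#' @param wave_amplitude_um sinusoidal centerline amplitude (micrometres).
#' @param wave_length_um sinusoidal period (micrometres, > 0).
#' @param split_prob per-fiber probability of one branch event in `[0, 1]`.
#' @param split_angle_rad divergence angle of a branch from its parent.
#' @param fiber_length_um mean fiber length (micrometres).
#' @param length_jitter relative half-width of the uniform length variation
#'   (0 renders every fiber at exactly `fiber_length_um`).
#' @param fiber_width_px Gaussian cross-section sigma in pixels.
#' @param noise_sd additive Gaussian background noise (intensity units).
#' @param shadow_count number of dark elliptical occluders.
#' @param seed integer RNG seed.
#' @param centers optional n x 2 matrix of fiber centres (row, col in pixels)
#'   to pin fiber placement; defaults to uniform random placement.
#' @return An object of class `fiber_scene_spec`.
#' @export
fiber_scene_spec <- function(image_size_px = c(384L, 384L),
                             pixel_size_um = 2,
                             n_fibers = 14L,
                             base_angle_rad = 1.2,
                             angle_jitter_rad = 0.04,
                             wave_amplitude_um = 0,
                             wave_length_um = 150,
                             split_prob = 0,
                             split_angle_rad = 0.5,
                             fiber_length_um = 450,
                             length_jitter = 0.25,
                             fiber_width_px = 2,
                             noise_sd = 0.02,
                             shadow_count = 0L,
                             seed = 1L,
                             centers = NULL) {
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 16),
            pixel_size_um > 0, n_fibers >= 0,
            wave_length_um > 0, split_prob >= 0, split_prob <= 1,
            wave_amplitude_um >= 0, fiber_length_um >= 0,
            length_jitter >= 0, length_jitter < 1,
            fiber_width_px > 0, noise_sd >= 0, shadow_count >= 0)
  spec <- list(image_size_px = as.integer(image_size_px),
               pixel_size_um = pixel_size_um, n_fibers = as.integer(n_fibers),
               base_angle_rad = base_angle_rad,
               angle_jitter_rad = angle_jitter_rad,
               wave_amplitude_um = wave_amplitude_um,
               wave_length_um = wave_length_um,
               split_prob = split_prob, split_angle_rad = split_angle_rad,
               fiber_length_um = fiber_length_um, length_jitter = length_jitter,
               fiber_width_px = fiber_width_px, noise_sd = noise_sd,
               shadow_count = as.integer(shadow_count), seed = as.integer(seed),
               centers = centers)
  class(spec) <- "fiber_scene_spec"
  spec
}

#' Analytic tortuosity of a sinusoidal centerline
#'
#' Arc length of `y = a sin(2 pi x / lambda)` over a whole number of periods,
#' by adaptive quadrature of `sqrt(1 + (2 pi a / lambda)^2 cos^2(2 pi x /
#' lambda))`, divided by the chord. For small `a / lambda` this approaches
#' `1 + pi^2 a^2 / lambda^2`.
#'
#' @param a_um amplitude in micrometres.
#' @param lambda_um period in micrometres (> 0).
#' @param length_um chord length, a whole number of periods.
#' @return Dimensionless tortuosity (>= 1).
#' @export
sine_tortuosity <- function(a_um, lambda_um, length_um) {
  stopifnot(lambda_um > 0, length_um > 0)
  if (a_um == 0) return(1)
  kk <- 2 * pi * a_um / lambda_um
  f <- function(x) sqrt(1 + kk^2 * cos(2 * pi * x / lambda_um)^2)
  arc <- stats::integrate(f, 0, length_um, rel.tol = 1e-10,
                          subdivisions = 1000L)$value
  arc / length_um
}

# Splat a polyline (n x 2 matrix, pixel row/col coordinates) of Gaussian
# cross-section sigma into accumulator `img`. Sample spacing ds (pixels)
# calibrates the peak of a straight ridge to `peak`.
.render_polyline <- function(img, pts_px, sigma, ds, peak = 1) {
  nr <- nrow(img); nc <- ncol(img)
  rad <- max(2L, as.integer(ceiling(3.5 * sigma)))
  win <- seq.int(-rad, rad)
  amp <- peak * ds / (sqrt(2 * pi) * sigma)
  for (i in seq_len(nrow(pts_px))) {
    r0 <- pts_px[i, 1L]; c0 <- pts_px[i, 2L]
    ri <- as.integer(round(r0)) + win
    ci <- as.integer(round(c0)) + win
    okr <- ri >= 1L & ri <= nr
    okc <- ci >= 1L & ci <= nc
    if (!any(okr) || !any(okc)) next
    ri <- ri[okr]; ci <- ci[okc]
    dr2 <- (ri - r0)^2
    dc2 <- (ci - c0)^2
    img[ri, ci] <- img[ri, ci] + amp * exp(-outer(dr2, dc2, `+`) / (2 * sigma^2))
  }
  img
}

# sample one fiber centerline; returns list(pts_um = n x 2 (row_um, col_um))
.sample_centerline <- function(center_um, theta, L_um, a_um, lambda_um,
                               phase, ds_um) {
  s <- seq(-L_um / 2, L_um / 2, by = ds_um)
  if (length(s) < 2L) s <- c(-L_um / 2, L_um / 2)
  wav <- if (a_um > 0) a_um * sin(2 * pi * s / lambda_um + phase) else rep(0, length(s))
  # tangent (col, row) = (cos theta, sin theta); normal = (-sin theta, cos theta)
  col_um <- center_um[2L] + s * cos(theta) - wav * sin(theta)
  row_um <- center_um[1L] + s * sin(theta) + wav * cos(theta)
  cbind(row_um, col_um)
}

#' Render a synthetic fiber scene
#'
#' Fibers are rendered additively as bright Gaussian-profile ridges (peak 1)
#' over a dark background, then multiplicative elliptical shadows and additive
#' Gaussian noise are applied and the result is clipped to `[0, 1]`.
#' Overlapping fibers merge brightly, mimicking touching fibers with low
#' inter-fiber contrast. The ground truth records every centerline polyline
#' (micron coordinates), its exact arc/chord tortuosity, chord orientation and
#' length, plus all split events. Fibers reaching the frame are clipped and
#' flagged.
#'
#' @param spec a [fiber_scene_spec()].
#' @return List of class `fiber_scene`: `image` (a [calibrated_image()]) and
#'   `truth` (list with `fibers` data frame, `polylines`, `splits`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "fiber_scene_spec"))
  nr <- spec$image_size_px[1L]; nc <- spec$image_size_px[2L]
  ps <- spec$pixel_size_um
  with_local_seed(spec$seed, {
    img <- matrix(0, nr, nc)
    ds_um <- 0.5 * ps
    fibers <- list()
    polylines <- list()
    splits <- list()
    for (i in seq_len(spec$n_fibers)) {
      theta <- spec$base_angle_rad +
        stats::runif(1, -spec$angle_jitter_rad, spec$angle_jitter_rad)
      L <- spec$fiber_length_um *
        (1 + stats::runif(1, -spec$length_jitter, spec$length_jitter))
      center <- if (!is.null(spec$centers)) {
        spec$centers[i, ] * ps
      } else {
        c(stats::runif(1, 1, nr) * ps, stats::runif(1, 1, nc) * ps)
      }
      phase <- stats::runif(1, 0, 2 * pi)
      pts <- .sample_centerline(center, theta, L, spec$wave_amplitude_um,
                                spec$wave_length_um, phase, ds_um)
      inside <- pts[, 1L] >= ps & pts[, 1L] <= nr * ps &
        pts[, 2L] >= ps & pts[, 2L] <= nc * ps
      clipped <- !all(inside)
      # keep the longest contiguous in-bounds run
      if (clipped) {
        r <- rle(inside)
        if (!any(r$values)) next
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        jbest <- which(r$values)[which.max(r$lengths[r$values])]
        pts <- pts[starts[jbest]:ends[jbest], , drop = FALSE]
      }
      if (nrow(pts) < 4L) next
      img <- .render_polyline(img, pts / ps, spec$fiber_width_px, ds_um / ps)
      chord <- sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
      arc <- path_length(pts)
      fibers[[length(fibers) + 1L]] <- data.frame(
        fiber_id = length(fibers) + 1L,
        orientation_rad = fold_angle(atan2(pts[nrow(pts), 1L] - pts[1L, 1L],
                                           pts[nrow(pts), 2L] - pts[1L, 2L])),
        length_um = arc,
        chord_um = chord,
        tortuosity = if (chord > 0) max(1, arc / chord) else NA_real_,
        clipped = clipped,
        stringsAsFactors = FALSE)
      polylines[[length(fibers)]] <- pts
      # optional branch event
      if (stats::runif(1) < spec$split_prob && nrow(pts) >= 8L) {
        j0 <- sample(seq.int(as.integer(nrow(pts) * 0.25),
                             as.integer(nrow(pts) * 0.75)), 1L)
        bdir <- theta + sample(c(-1, 1), 1L) * spec$split_angle_rad
        bl <- L * stats::runif(1, 0.3, 0.5)
        bs <- seq(0, bl, by = ds_um)
        bpts <- cbind(pts[j0, 1L] + bs * sin(bdir),
                      pts[j0, 2L] + bs * cos(bdir))
        bin <- bpts[, 1L] >= ps & bpts[, 1L] <= nr * ps &
          bpts[, 2L] >= ps & bpts[, 2L] <= nc * ps
        bpts <- bpts[bin, , drop = FALSE]
        if (nrow(bpts) >= 4L) {
          img <- .render_polyline(img, bpts / ps, spec$fiber_width_px, ds_um / ps)
          splits[[length(splits) + 1L]] <- list(
            fiber_id = length(fibers),
            at_um = pts[j0, ],
            angle_rad = fold_angle(bdir),
            polyline = bpts)
        }
      }
    }
    img[img > 1] <- 1
    # multiplicative dark elliptical occluders
    if (spec$shadow_count > 0L) {
      rr <- matrix(seq_len(nr), nr, nc)
      cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      for (k in seq_len(spec$shadow_count)) {
        ctr <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
        ax <- stats::runif(2, 15, 55)
        ang <- stats::runif(1, 0, pi)
        dx <- (rr - ctr[1L]) * cos(ang) + (cc - ctr[2L]) * sin(ang)
        dy <- -(rr - ctr[1L]) * sin(ang) + (cc - ctr[2L]) * cos(ang)
        inside <- (dx / ax[1L])^2 + (dy / ax[2L])^2 <= 1
        img[inside] <- img[inside] * 0.35
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    truth <- list(
      fibers = if (length(fibers)) do.call(rbind, fibers) else
        data.frame(fiber_id = integer(0), orientation_rad = numeric(0),
                   length_um = numeric(0), chord_um = numeric(0),
                   tortuosity = numeric(0), clipped = logical(0)),
      polylines = polylines,
      splits = splits)
    structure(list(image = calibrated_image(img, ps, sprintf("synthetic-seed%d", spec$seed)),
                   truth = truth, spec = spec),
              class = "fiber_scene")
  })
}

#' Built-in cohort profiles
#'
#' Parameter sets emulating the three study arms: `acute_like` (long,
#' straight, parallel fibers — the healthy-regeneration comparator),
#' `chronic_like` (shorter, wavy, split, dispersed fibers — poor
#' regeneration), and `treated_like` (intermediate). All scenes share the
#' frame (384 x 384 px at 2 um/px) and rendering parameters; only the
#' morphology parameters differ.
#'
#' @return Named list of [fiber_scene_spec()] argument lists.
#' @export
fiber_profiles <- function() {
  base <- list(image_size_px = c(384L, 384L), pixel_size_um = 2,
               n_fibers = 14L, base_angle_rad = 1.2, fiber_width_px = 2,
               noise_sd = 0.02, shadow_count = 0L, wave_length_um = 120)
  list(
    acute_like = utils::modifyList(base, list(
      angle_jitter_rad = 0.04, wave_amplitude_um = 0,
      split_prob = 0, fiber_length_um = 450)),
    chronic_like = utils::modifyList(base, list(
      angle_jitter_rad = 0.45, wave_amplitude_um = 7,
      split_prob = 0.5, split_angle_rad = 0.5, fiber_length_um = 200)),
    treated_like = utils::modifyList(base, list(
      angle_jitter_rad = 0.20, wave_amplitude_um = 3,
      split_prob = 0.2, split_angle_rad = 0.5, fiber_length_um = 320))
  )
}

#' Generate a cohort of synthetic images for one group profile
#'
#' @param profile `"acute_like"`, `"chronic_like"` or `"treated_like"`.
#' @param n_images number of images (>= 1).
#' @param seed integer; image `j` uses a seed derived from `seed` and `j`.
#' @param ... overrides passed to [fiber_scene_spec()].
#' @return List of class `fiber_cohort` of `fiber_scene` objects, each with a
#'   `group` label attached.
#' @export
make_group_cohort <- function(profile = c("acute_like", "chronic_like", "treated_like"),
                              n_images, seed = 1L, ...) {
  profile <- match.arg(profile)
  if (n_images < 1L) stop("n_images must be >= 1")
  params <- fiber_profiles()[[profile]]
  params <- utils::modifyList(params, list(...))
  scenes <- lapply(seq_len(n_images), function(j) {
    params$seed <- (abs(as.integer(seed)) %% 1000000L) * 1000L + j
    sc <- generate_scene(do.call(fiber_scene_spec, params))
    sc$group <- profile
    sc
  })
  class(scenes) <- "fiber_cohort"
  attr(scenes, "profile") <- profile
  scenes
}
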