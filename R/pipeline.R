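# End-to-end orchestration: image -> probability -> thin edges -> skeleton ->
# segments -> biomarkers.

#' Pipeline configuration
#'
#' Validates every stage parameter up front; each has a documented default.
#'
#' @param backend `"gradient"` (classical gradient-magnitude map),
#'   `"probfile"` (externally produced probability map, see `probmap_path` /
#'   `invert`), or `"intensity"` (rescaled image intensity used directly as
#'   the probability surface — appropriate for ridge-like inputs such as
#'   synthetic scenes or pre-rendered detector outputs).
#' @param smooth_sigma_px Gaussian scale for the gradient backend and for
#'   orientation estimation (pixels).
#' @param nms_tolerance plateau tie tolerance of non-maximum suppression.
#' @param probmap_path grayscale file for the `probfile` backend.
#' @param invert complement a loaded probability map (white-background maps).
#' @param tl,th double-threshold bounds on the `[0, 1]` probability scale.
#' @param hysteresis `"transitive"` (default) or `"one_hop"`.
#' @param margin_px border margin discarded from the skeleton.
#' @param min_length_um,min_chord_um segment exclusion filters (micrometres).
#' @param smooth_window_px path-smoothing window for arc-length measurement.
#' @param resize_factor optional composite downscaling in (0, 1].
#' @param channel_merge `"max"` or `"luminance"` multi-channel projection.
#' @param channel_means optional per-channel means subtracted during
#'   preprocessing.
#' @param recenter_axial recentre orientation angles before dispersion stats.
#' @param seed seed for any stochastic stage (the analysis itself is
#'   deterministic; only synthetic generation consumes randomness).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(backend = c("gradient", "probfile", "intensity"),
                            smooth_sigma_px = 2,
                            nms_tolerance = 1.01,
                            probmap_path = NULL,
                            invert = FALSE,
                            tl = 0.1, th = 0.3,
                            hysteresis = c("transitive", "one_hop"),
                            margin_px = 10,
                            min_length_um = 100,
                            min_chord_um = 50,
                            smooth_window_px = 5,
                            resize_factor = 1,
                            channel_merge = c("max", "luminance"),
                            channel_means = NULL,
                            recenter_axial = FALSE,
                            seed = 1L) {
  backend <- match.arg(backend)
  hysteresis <- match.arg(hysteresis)
  channel_merge <- match.arg(channel_merge)
  stopifnot(smooth_sigma_px > 0, nms_tolerance >= 1,
            tl >= 0, th <= 1, tl < th,
            margin_px >= 0, min_length_um >= 0, min_chord_um >= 0,
            smooth_window_px >= 1,
            resize_factor > 0, resize_factor <= 1)
  structure(list(backend = backend, smooth_sigma_px = smooth_sigma_px,
                 nms_tolerance = nms_tolerance, probmap_path = probmap_path,
                 invert = invert, tl = tl, th = th, hysteresis = hysteresis,
                 margin_px = margin_px, min_length_um = min_length_um,
                 min_chord_um = min_chord_um,
                 smooth_window_px = smooth_window_px,
                 resize_factor = resize_factor, channel_merge = channel_merge,
                 channel_means = channel_means,
                 recenter_axial = recenter_axial, seed = seed),
            class = "pipeline_config")
}

#' Run the full quantification pipeline on one image
#'
#' Stage order: preprocess -> probability -> non-maximum suppression ->
#' double threshold -> hysteresis -> skeletonize -> clear border -> graph ->
#' filter -> biomarkers. Deterministic for fixed config and input. Per-stage
#' pixel/segment counts are logged in the result.
#'
#' @param x a [calibrated_image()], a `fiber_scene`, an [edge_prob_map()], or
#'   a file path (requires `pixel_size_um`).
#' @param config a [pipeline_config()].
#' @param pixel_size_um calibration, required when `x` is a file path.
#' @param group group label carried into the biomarker row.
#' @param keep_intermediate keep the stage outputs (maps, masks, skeleton) in
#'   the result.
#' @return Object of class `fiber_pipeline_result`: `biomarkers` (one row),
#'   `graph` (filtered `skeleton_graph`), `graph_unfiltered`, `log` (stage
#'   count table), `config`, and optionally `stages`.
#' @export
run_pipeline <- function(x, config = pipeline_config(), pixel_size_um = NULL,
                         group = NA_character_, keep_intermediate = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(x, "fiber_scene")) {
    if (is.na(group) && !is.null(x$group)) group <- x$group
    x <- x$image
  }
  if (is.character(x)) {
    if (is.null(pixel_size_um)) stop("pixel_size_um required when reading from file")
    x <- read_image(x, pixel_size_um)
  }
  log <- list()
  note <- function(stage, count) log[[length(log) + 1L]] <<- data.frame(
    stage = stage, count = count, stringsAsFactors = FALSE)
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (inherits(x, "edge_prob_map")) {
    P <- x
    note("probability", sum(P$prob > 0))
  } else {
    stopifnot(inherits(x, "calibrated_image"))
    img <- stage_wrap("preprocess", {
      out <- x
      if (config$resize_factor < 1 || !is.null(config$channel_means)) {
        out <- preprocess_composite(out, config$resize_factor, config$channel_means)
      }
      merge_channels(out, config$channel_merge)
    })
    note("preprocess", prod(dim(img$pixels)[1:2]))
    P <- stage_wrap("probability", switch(
      config$backend,
      gradient = gradient_edge_probability(img, config$smooth_sigma_px),
      intensity = intensity_probability(img),
      probfile = {
        if (is.null(config$probmap_path)) stop("probfile backend needs probmap_path")
        load_probability_map(config$probmap_path, config$invert, img$pixel_size_um)
      }))
    note("probability", sum(P$prob > 0))
  }

  O <- stage_wrap("orientation", estimate_orientation(P, config$smooth_sigma_px))
  E <- stage_wrap("nms", nonmax_suppress(P, O, config$nms_tolerance))
  note("nms", sum(E$prob > 0))
  L <- stage_wrap("double_threshold", double_threshold(E, config$tl, config$th))
  note("double_threshold_strong", sum(L$labels == 2L))
  B <- stage_wrap("hysteresis", hysteresis_track(L, config$hysteresis))
  note("hysteresis", sum(B$mask))
  S <- stage_wrap("skeletonize", skeletonize(B))
  note("skeletonize", sum(S$mask))
  S <- stage_wrap("clear_border", clear_border(S, config$margin_px))
  note("clear_border", sum(S$mask))
  G0 <- stage_wrap("graph", build_graph(S, smooth_window = config$smooth_window_px))
  note("segments", nrow(G0$segments))
  G <- stage_wrap("filter", filter_segments(G0, config$min_length_um, config$min_chord_um))
  note("segments_filtered", nrow(G$segments))
  bm <- stage_wrap("biomarkers",
                   compute_biomarkers(G, group = group,
                                      recenter_axial = config$recenter_axial))
  res <- list(biomarkers = bm, graph = G, graph_unfiltered = G0,
              log = do.call(rbind, log), config = config)
  if (keep_intermediate) {
    res$stages <- list(probability = P, orientation = O, thin = E,
                       labels = L, mask = B, skeleton = S)
  }
  class(res) <- "fiber_pipeline_result"
  res
}

#' @export
print.fiber_pipeline_result <- function(x, ...) {
  cat("<fiber_pipeline_result>\n")
  print(x$log, row.names = FALSE)
  cat("\nBiomarkers:\n")
  print(as.data.frame(x$biomarkers), row.names = FALSE)
  invisible(x)
}

#' @export
summary.fiber_pipeline_result <- function(object, ...) {
  print(object)
  invisible(object$biomarkers)
}

#' Run the pipeline over a cohort of scenes or a manifest of files
#'
#' @param cohort a `fiber_cohort` (see [make_group_cohort()]), a list of
#'   `fiber_scene`s, or a `group_manifest` data frame.
#' @param config a [pipeline_config()].
#' @param pixel_size_um calibration for manifest file paths.
#' @return Data frame of stacked biomarker rows, one per image.
#' @export
run_cohort <- function(cohort, config = pipeline_config(), pixel_size_um = NULL) {
  if (inherits(cohort, "group_manifest")) {
    rows <- lapply(seq_len(nrow(cohort)), function(i) {
      run_pipeline(cohort$path[i], config, pixel_size_um = pixel_size_um,
                   group = cohort$group[i])$biomarkers
    })
  } else {
    rows <- lapply(cohort, function(sc) run_pipeline(sc, config)$biomarkers)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("biomarker_table", "data.frame")
  out
}

.CATEGORY_COLORS <- c(endpoint_to_endpoint = "#E41A1C",
                      junction_to_endpoint = "#4DAF4A",
                      junction_to_junction = "#377EB8",
                      isolated_cycle = "#FF7F00")

#' Overlay traced segments on the source image
#'
#' Writes a PNG with the (contrast-stretched, grayscale) source and the
#' traced segment pixels recoloured, one colour per segment category.
#'
#' @param img the source [calibrated_image()].
#' @param G a `skeleton_graph` whose paths lie within the image bounds.
#' @param out_path output PNG path.
#' @return `out_path`, invisibly.
#' @export
overlay <- function(img, G, out_path) {
  base <- merge_channels(img)$pixels
  rng <- range(base)
  if (diff(rng) > 0) base <- (base - rng[1]) / diff(rng)
  rgb <- array(rep(base, 3L), c(dim(base), 3L))
  cols <- grDevices::col2rgb(.CATEGORY_COLORS) / 255
  for (i in seq_along(G$paths)) {
    p <- G$paths[[i]]
    if (is.null(p)) next
    if (any(p[, 1L] < 1 | p[, 1L] > nrow(base) |
            p[, 2L] < 1 | p[, 2L] > ncol(base))) {
      stop("segment path out of image bounds")
    }
    colv <- cols[, G$segments$category[i]]
    for (ch in 1:3) {
      rgb[cbind(p[, 1L], p[, 2L], ch)] <- colv[ch]
    }
  }
  png::writePNG(rgb, out_path)
  invisible(out_path)
}

#' @export
plot.fiber_pipeline_result <- function(x, ...) {
  G <- x$graph
  d <- G$dim %||% c(100L, 100L)
  graphics::plot(NA, xlim = c(1, d[2]), ylim = c(d[1], 1), asp = 1,
                 xlab = "col (px)", ylab = "row (px)", ...)
  for (i in seq_along(G$paths)) {
    p <- G$paths[[i]]
    if (is.null(p)) next
    graphics::lines(p[, 2L], p[, 1L],
                    col = .CATEGORY_COLORS[G$segments$category[i]], lwd = 2)
  }
  invisible(x)
}
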