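#' Calibrated micrograph
#'
#' A pixel grid (matrix, or array with a channel dimension) together with the
#' physical edge length of one pixel in micrometres. All micron quantities
#' downstream (segment lengths, areas, filters) derive from this calibration,
#' which must be supplied by the user: it is never guessed from file metadata.
#'
#' @param pixels numeric matrix (rows x cols) or array (rows x cols x channels).
#' @param pixel_size_um physical edge length of one pixel in micrometres (> 0).
#' @param source_id free-text provenance label.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um, source_id = "") {
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  d <- dim(pixels)
  if (is.null(d) || length(d) < 2L || d[1] < 2L || d[2] < 2L) {
    stop("pixels must have at least 2 rows and 2 columns")
  }
  if (length(d) > 3L) stop("pixels must be 2-D or 2-D x channels")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("calibration error: pixel_size_um must be a single positive number")
  }
  structure(list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
                 source_id = as.character(source_id)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  ch <- if (length(d) == 3L) d[3] else 1L
  cat(sprintf("<calibrated_image> %d x %d px, %d channel(s), %.4g um/px",
              d[1], d[2], ch, x$pixel_size_um))
  if (nzchar(x$source_id)) cat(" [", x$source_id, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Read a micrograph from TIFF, PNG or JPEG
#'
#' Integer intensities are preserved bit-exactly (an 8-bit file yields values
#' 0..255, a 16-bit file 0..65535). Floating-point TIFFs are returned as
#' stored. JPEG decoding requires the EBImage package.
#'
#' @param path image file (extension decides the decoder).
#' @param pixel_size_um calibration in micrometres per pixel (> 0).
#' @param source_id provenance label; defaults to the file name.
#' @return A [calibrated_image()] with attribute `max_value` (the format's
#'   full-scale value, used when reinterpreting the image as a probability map).
#' @export
read_image <- function(path, pixel_size_um, source_id = basename(path)) {
  if (!file.exists(path)) stop("missing file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    px <- png::readPNG(path, info = TRUE)
    depth <- attr(px, "info")$bit.depth %||% 8L
    maxv <- 2^depth - 1
    pixels <- round(unclass(px) * maxv)
    attr(pixels, "info") <- NULL
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    if (is.list(px)) px <- px[[1L]]
    bits <- attr(px, "bits.per.sample") %||% 8L
    if (bits >= 32L) {
      maxv <- 1                      # floating-point samples, kept as stored
      pixels <- px
    } else if (max(px) <= 1 && !all(px == round(px))) {
      # decoder returned normalized values (multi-channel path): restore ints
      maxv <- 2^bits - 1
      pixels <- round(px * maxv)
    } else {
      maxv <- 2^bits - 1
      pixels <- px
    }
    d <- dim(pixels)
    attributes(pixels) <- NULL
    dim(pixels) <- d
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG decoding requires the EBImage package")
    }
    e <- EBImage::readImage(path)
    d <- dim(e)
    a <- EBImage::imageData(e)
    pixels <- if (length(d) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    pixels <- round(pixels * 255)
    maxv <- 255
  } else {
    stop("undecodable format: ", ext)
  }
  # drop a trailing singleton channel dimension
  if (length(dim(pixels)) == 3L && dim(pixels)[3] == 1L) {
    pixels <- array(pixels, dim(pixels)[1:2])
  }
  img <- calibrated_image(pixels, pixel_size_um, source_id)
  attr(img, "max_value") <- maxv
  img
}

#' Write a single-plane image as PNG (8-bit) for inspection
#'
#' Values are clipped to `[0, 1]` after division by `max(x)` unless already in
#' range.
#' @param pixels numeric matrix, or a `calibrated_image`.
#' @param path output file path (.png).
#' @export
write_image_png <- function(pixels, path) {
  if (inherits(pixels, "calibrated_image")) pixels <- pixels$pixels
  if (length(dim(pixels)) == 2L) {
    mx <- max(pixels)
    if (mx > 1) pixels <- pixels / mx
    pixels[pixels < 0] <- 0
  }
  png::writePNG(pixels, path)
  invisible(path)
}

#' Flatten a multi-channel composite to one intensity plane
#'
#' Confetti-style composites carry lineage colour that is irrelevant to edge
#' morphology; the default channel-max projection keeps each fiber at its
#' brightest fluorophore. `"luminance"` applies Rec. 709 weights (first three
#' channels) instead.
#'
#' @param img a [calibrated_image()].
#' @param mode `"max"` (default) or `"luminance"`.
#' @return A single-plane `calibrated_image`.
#' @export
merge_channels <- function(img, mode = c("max", "luminance")) {
  mode <- match.arg(mode)
  px <- img$pixels
  if (length(dim(px)) == 2L) return(img)
  if (mode == "max") {
    flat <- apply(px, c(1, 2), max)
  } else {
    if (dim(px)[3] < 3L) {
      flat <- apply(px, c(1, 2), mean)
    } else {
      flat <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
    }
  }
  out <- calibrated_image(flat, img$pixel_size_um, img$source_id)
  attr(out, "max_value") <- attr(img, "max_value")
  out
}

#' Resize and channel-normalize a composite image
#'
#' Downscaling uses bilinear interpolation after a mild anti-aliasing blur
#' (sigma `(1/f - 1)/2` pixels). The physical field of view is conserved:
#' the output calibration is `pixel_size_um / resize_factor`. If
#' `channel_means` is given, each channel has that constant subtracted
#' (values may become negative; probability backends rescale).
#'
#' @param img a [calibrated_image()].
#' @param resize_factor scale in (0, 1]; 0.5 halves each dimension.
#' @param channel_means optional numeric vector, one mean per channel.
#' @return A `calibrated_image`.
#' @export
preprocess_composite <- function(img, resize_factor = 0.5, channel_means = NULL) {
  if (!is.numeric(resize_factor) || length(resize_factor) != 1L ||
      resize_factor <= 0 || resize_factor > 1) {
    stop("resize_factor must be in (0, 1]")
  }
  px <- img$pixels
  d <- dim(px)
  nch <- if (length(d) == 3L) d[3] else 1L
  as_planes <- function(p) if (nch == 1L) list(p) else lapply(seq_len(nch), function(k) p[, , k])
  planes <- as_planes(px)
  if (resize_factor < 1) {
    aa_sigma <- (1 / resize_factor - 1) / 2
    nr2 <- max(2L, as.integer(round(d[1] * resize_factor)))
    nc2 <- max(2L, as.integer(round(d[2] * resize_factor)))
    # output pixel centres mapped back into source coordinates
    src_r <- (seq_len(nr2) - 0.5) / resize_factor + 0.5
    src_c <- (seq_len(nc2) - 0.5) / resize_factor + 0.5
    src_r <- pmin(pmax(src_r, 1), d[1])
    src_c <- pmin(pmax(src_c, 1), d[2])
    rr <- rep(src_r, times = nc2)
    cc <- rep(src_c, each = nr2)
    planes <- lapply(planes, function(p) {
      sm <- if (aa_sigma > 0.1) gaussian_blur(p, aa_sigma) else p
      matrix(bilinear_sample(sm, rr, cc), nr2, nc2)
    })
  }
  if (!is.null(channel_means)) {
    if (length(channel_means) != nch) stop("channel_means must have one value per channel")
    planes <- Map(function(p, m) p - m, planes, as.list(as.numeric(channel_means)))
  }
  out_px <- if (nch == 1L) planes[[1L]] else {
    array(unlist(planes), c(dim(planes[[1L]]), nch))
  }
  out <- calibrated_image(out_px, img$pixel_size_um / resize_factor, img$source_id)
  attr(out, "max_value") <- attr(img, "max_value")
  out
}

#' Write / read a per-image biomarker table
#'
#' One CSV row per image, one column per biomarker plus the group label.
#' Numeric values survive the round trip to at least 12 significant digits.
#'
#' @param records a data frame of biomarker rows (see [compute_biomarkers()]).
#' @param path output CSV path.
#' @export
write_results <- function(records, path) {
  if (is.null(records) || !is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data frame")
  }
  utils::write.csv(format(records, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("missing results file: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("biomarker_table", "data.frame")
  out
}

#' Read a group manifest CSV
#'
#' Two columns: `path` (unique image file paths) and `group` (treatment label).
#' @param path manifest CSV.
#' @return data frame of class `group_manifest`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "group") %in% names(m))) {
    stop("manifest needs 'path' and 'group' columns")
  }
  if (anyDuplicated(m$path)) stop("manifest paths must be unique")
  class(m) <- c("group_manifest", "data.frame")
  m
}
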