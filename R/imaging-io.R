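#' @useDynLib erpuncta, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Calibrated 2D fluorescence image
#'
#' A single-channel 2D intensity grid together with its physical pixel size.
#' All downstream area and velocity computations take their calibration from
#' this object. Coordinates follow the convention that pixel `[i, j]` (1-based
#' row/column) covers the physical square with centre
#' `((j - 0.5) * pixel_size_um, (i - 0.5) * pixel_size_um)` in (x, y).
#'
#' @param pixels numeric matrix of non-negative intensities (arbitrary units).
#' @param pixel_size_um physical edge length of one pixel, in micrometres.
#' @param channel_name optional channel label (e.g. `"target"`, `"site"`).
#' @param time_s optional acquisition time stamp in seconds.
#' @return An object of class `CalibratedImage`.
#' @examples
#' img <- calibrated_image(matrix(0, 4, 4), pixel_size_um = 0.15)
#' img$pixel_size_um
#' @export
calibrated_image <- function(pixels, pixel_size_um, channel_name = NA_character_,
                             time_s = NA_real_) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (length(pixels) == 0L) stop("image grid must be non-empty")
  if (anyNA(pixels) || any(pixels < 0)) stop("intensities must be non-negative and finite")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         channel_name = as.character(channel_name), time_s = as.numeric(time_s)),
    class = "CalibratedImage"
  )
}

#' @export
print.CalibratedImage <- function(x, ...) {
  cat(sprintf("CalibratedImage: %d x %d px, %.4g um/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$channel_name))
  invisible(x)
}

#' Boolean region-of-interest mask
#'
#' A boolean grid congruent with an image, used for cell outlines, hand-drawn
#' background rectangles, thresholded site masks and puncta masks. Background
#' masks are required to be disjoint from the cell they calibrate, mirroring
#' the convention of drawing the background ROI in a dark extracellular region.
#'
#' @param pixels logical matrix (or coercible 0/1 matrix).
#' @param kind one of `"cell"`, `"background"`, `"site"`, `"puncta"`.
#' @return An object of class `RegionMask`.
#' @export
region_mask <- function(pixels, kind = c("puncta", "cell", "background", "site")) {
  kind <- match.arg(kind)
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("mask grid must be non-empty")
  if (!is.logical(pixels)) {
    if (anyNA(pixels)) stop("mask may not contain NA")
    pixels <- pixels != 0
  }
  structure(list(pixels = pixels, kind = kind), class = "RegionMask")
}

#' @export
print.RegionMask <- function(x, ...) {
  cat(sprintf("RegionMask (%s): %d x %d px, %d foreground\n",
              x$kind, nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

# pull the pixel matrix out of an image/mask/matrix argument
.as_pixels <- function(x) {
  if (inherits(x, "CalibratedImage") || inherits(x, "RegionMask")) return(x$pixels)
  as.matrix(x)
}

.check_congruent <- function(a, b) {
  a <- .as_pixels(a); b <- .as_pixels(b)
  if (!identical(dim(a), dim(b))) stop("grids are not congruent (shape mismatch)")
  invisible(TRUE)
}

#' Read a TIFF image as calibrated channel(s)
#'
#' Reads single- or multi-page TIFF files. Each page is returned as one
#' [calibrated_image()]; multi-channel acquisitions are stored one channel per
#' page (the channel axis is never inferred from pixel statistics). Integer
#' TIFFs are returned in native integer intensity units; floating-point TIFFs
#' on the normalized `[0, 1]` scale.
#'
#' The pixel size is taken from `pixel_size_um` when supplied, otherwise from
#' the TIFF x-resolution tag (pixels per micrometre or per centimetre,
#' depending on the resolution unit); if neither is available the read fails,
#' because uncalibrated images cannot support area or velocity measurements.
#'
#' @param path path to a readable TIFF file.
#' @param pixel_size_um optional calibration override in micrometres.
#' @param channel_names optional character vector naming the pages.
#' @return A list of `CalibratedImage`, one per page/channel.
#' @export
read_image <- function(path, pixel_size_um = NULL, channel_names = NULL) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  info <- tryCatch(tiff::readTIFF(path, info = TRUE, payload = FALSE),
                   error = function(e) stop("unreadable TIFF: ", conditionMessage(e)))
  bits <- info$bits.per.sample
  as_is <- is.null(bits) || bits <= 16          # float pages stay on [0,1]
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = as_is),
                    error = function(e) stop("unreadable TIFF: ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(pixel_size_um)) {
    xres <- info$x.resolution
    if (is.null(xres) || !is.finite(xres) || xres <= 0) {
      stop("no pixel calibration: supply pixel_size_um (file carries no resolution tag)")
    }
    unit <- if (is.null(info$resolution.unit)) "none" else info$resolution.unit
    # resolution is pixels per unit; "cm" tags give px/cm, otherwise px/um assumed
    pixel_size_um <- if (identical(unit, "cm")) 1e4 / xres else 1 / xres
  }
  lapply(seq_along(pages), function(i) {
    px <- pages[[i]]
    if (length(dim(px)) == 3L) px <- px[, , 1L]   # collapse redundant samples
    nm <- if (!is.null(channel_names) && i <= length(channel_names)) {
      channel_names[i]
    } else {
      NA_character_
    }
    calibrated_image(px, pixel_size_um, channel_name = nm)
  })
}

#' Write a calibrated image to TIFF
#'
#' Integer-valued images (camera ADU, the generator's native output) are
#' written as 16-bit TIFF and round-trip exactly for values in 0..65535.
#' Non-integer data must lie in `[0, 1]` and is written as 32-bit float.
#'
#' @param image a [calibrated_image()] or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- .as_pixels(image)
  if (all(px == round(px))) {
    if (any(px < 0) || any(px > 65535)) stop("integer image out of 16-bit range")
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  } else {
    if (any(px < 0) || any(px > 1)) stop("float images must lie in [0, 1]")
    tiff::writeTIFF(px, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Write / read a boolean mask as an 8-bit TIFF
#'
#' @param mask a [region_mask()] or logical matrix.
#' @param path file path.
#' @return `write_mask` returns `path` invisibly; `read_mask` a `RegionMask`.
#' @export
write_mask <- function(mask, path) {
  px <- .as_pixels(mask)
  tiff::writeTIFF((px != 0) * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @param kind mask kind passed to [region_mask()].
#' @export
read_mask <- function(path, kind = "puncta") {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  region_mask(px > 0, kind = kind)
}

#' Write tabular results to CSV
#'
#' Column order is preserved as given; numeric fields round-trip to at least
#' 10 significant digits.
#'
#' @param records non-empty data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tables <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L || ncol(records) == 0L) {
    stop("refusing to write an empty table")
  }
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], function(x) {
    # format() keeps full double precision; write.csv would too, but be explicit
    as.numeric(format(x, digits = 15, scientific = NA))
  })
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tables
#' @export
read_tables <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
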