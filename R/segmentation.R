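#' Size bins for puncta classification
#'
#' The three area classes used throughout this workflow, plus the independent
#' "large punctum" flag. Bin B1 is `[0, 0.12)` um^2, B2 is the closed interval
#' `[0.12, 0.24]` um^2 ("0.12-0.24" read literally, closed on both sides), and
#' B3 is `(0.24, Inf)`. A punctum is "large" when its area is >= 0.5 um^2;
#' the large flag is applied independently of the three bins (every large
#' punctum necessarily falls in B3).
#'
#' @param small_max upper (open) edge of B1 in um^2.
#' @param mid_max upper (closed) edge of B2 in um^2.
#' @param large_min inclusive threshold for the large flag in um^2.
#' @return A list with the bin edges, class `SizeBinning`.
#' @export
size_bins <- function(small_max = 0.12, mid_max = 0.24, large_min = 0.5) {
  stopifnot(small_max > 0, mid_max > small_max, large_min > mid_max)
  structure(list(small_max = small_max, mid_max = mid_max, large_min = large_min),
            class = "SizeBinning")
}

#' Yen entropy auto-threshold
#'
#' Computes the automatic threshold of Yen's maximum-correlation criterion on
#' a 256-bin histogram spanning `[min, max]` of the image, the binarization
#' step used to identify puncta (it captures isolated spots as well as
#' punctate accentuations on tubules). Ties in the criterion are broken
#' toward the lower level so results are deterministic. Pixels strictly above
#' the returned intensity are foreground.
#'
#' @param image a [calibrated_image()] or numeric matrix with at least two
#'   distinct intensity values.
#' @param n_bins number of histogram bins (256 matches the 8-bit behaviour of
#'   the original tool regardless of input bit depth).
#' @return The threshold as a single intensity value (same units as the
#'   image), equal to the upper edge of the argmax histogram bin.
#' @examples
#' x <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
#' thr <- yen_threshold(x)
#' sum(x > thr) == 50
#' @export
yen_threshold <- function(image, n_bins = 256L) {
  x <- .as_pixels(image)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("constant image: no threshold exists")
  w <- (hi - lo) / n_bins
  b <- pmin(n_bins - 1L, floor((x - lo) / w))
  p <- tabulate(b + 1L, nbins = n_bins) / length(x)
  crit <- .yen_criterion(p)
  # ties (within numerical tolerance) break toward the lower level
  t_star <- which(crit >= max(crit) - 1e-10)[1L]
  lo + t_star * w
}

# Yen's maximum correlation criterion evaluated at every histogram level t
# (background = bins 1..t). Terms with non-positive arguments contribute 0.
.yen_criterion <- function(p) {
  P1 <- cumsum(p)
  P2 <- cumsum(p^2)
  P2c <- sum(p^2) - P2
  t1 <- ifelse(P2 * P2c > 0, -log(P2 * P2c), 0)
  t2 <- ifelse(P1 * (1 - P1) > 0, 2 * log(P1 * (1 - P1)), 0)
  t1 + t2
}

# polygon perimeter of the outer boundary of each labelled object,
# via oriented contour tracing; single-pixel objects have perimeter 0
.object_perimeters <- function(label_map) {
  n_obj <- max(label_map)
  if (n_obj == 0L) return(numeric(0))
  oc <- EBImage::ocontour(label_map)
  per <- numeric(n_obj)
  ids <- as.integer(names(oc))
  for (k in seq_along(oc)) {
    pts <- oc[[k]]
    if (nrow(pts) < 2L) { per[ids[k]] <- 0; next }
    closed <- rbind(pts, pts[1L, , drop = FALSE])
    per[ids[k]] <- sum(sqrt(rowSums(diff(closed)^2)))
  }
  per
}

#' Particle analysis of a binary mask
#'
#' Finds 8-connected components of a thresholded mask, measures each object's
#' calibrated area, centroid, circularity and (optionally) mean intensity,
#' and retains the objects passing the area and circularity filters. The
#' remaining objects are relabelled consecutively. Holes in objects are not
#' filled.
#'
#' Circularity is `min(1, 4 * pi * area / perimeter^2)` with the perimeter
#' estimated as the polygon length of the traced outer boundary (1 per
#' axial step, `sqrt(2)` per diagonal step); objects too small to trace
#' (single pixels) are assigned circularity 1.
#'
#' @param mask a [region_mask()] or logical matrix of foreground pixels.
#' @param pixel_size_um calibration in micrometres per pixel.
#' @param size_range_um2 inclusive `[min, max]` area filter in um^2.
#' @param circularity_range inclusive `[min, max]` circularity filter; the
#'   default 0.5-1 is the puncta-shape criterion of this workflow.
#' @param image optional [calibrated_image()] (or matrix) from which each
#'   object's mean intensity is measured.
#' @return An object of class `PunctaSet`: a list with `label_map` (integer
#'   matrix, 0 = background), `records` (one row per retained object: `id`,
#'   `n_px`, `area_um2`, `centroid_x_um`, `centroid_y_um`, `circularity`,
#'   `mean_intensity`), `pixel_size_um`, and `n_discarded`.
#' @export
analyze_particles <- function(mask, pixel_size_um,
                              size_range_um2 = c(0, Inf),
                              circularity_range = c(0.5, 1),
                              image = NULL) {
  px <- .as_pixels(mask)
  if (!is.null(image)) .check_congruent(px, image)
  stopifnot(pixel_size_um > 0)
  lab <- cc_label8(px != 0)
  n_obj <- max(lab)
  empty <- data.frame(id = integer(0), n_px = integer(0), area_um2 = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      circularity = numeric(0), mean_intensity = numeric(0))
  if (n_obj == 0L) {
    return(structure(list(label_map = lab, records = empty,
                          pixel_size_um = pixel_size_um, n_discarded = 0L),
                     class = "PunctaSet"))
  }
  idx <- which(lab > 0L)
  ids <- lab[idx]
  n_px <- tabulate(ids, n_obj)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  # physical centroid: pixel centre at (index - 0.5) * pixel size
  cy <- (vapply(split(rows, ids), mean, 0) - 0.5) * pixel_size_um
  cx <- (vapply(split(cols, ids), mean, 0) - 0.5) * pixel_size_um
  per <- .object_perimeters(lab)
  circ <- ifelse(per > 0, pmin(1, 4 * pi * n_px / per^2), 1)
  area <- n_px * pixel_size_um^2
  mint <- if (is.null(image)) {
    rep(NA_real_, n_obj)
  } else {
    im <- .as_pixels(image)
    vapply(split(im[idx], ids), mean, 0)
  }
  keep <- area >= size_range_um2[1] & area <= size_range_um2[2] &
    circ >= circularity_range[1] & circ <= circularity_range[2]
  old_ids <- which(keep)
  remap <- integer(n_obj)
  remap[old_ids] <- seq_along(old_ids)
  new_lab <- lab
  new_lab[idx] <- remap[ids]
  records <- data.frame(
    id = seq_along(old_ids), n_px = n_px[old_ids], area_um2 = area[old_ids],
    centroid_x_um = unname(cx[old_ids]), centroid_y_um = unname(cy[old_ids]),
    circularity = unname(circ[old_ids]), mean_intensity = unname(mint[old_ids])
  )
  structure(list(label_map = new_lab, records = records,
                 pixel_size_um = pixel_size_um,
                 n_discarded = as.integer(n_obj - length(old_ids))),
            class = "PunctaSet")
}

#' @export
print.PunctaSet <- function(x, ...) {
  cat(sprintf("PunctaSet: %d objects (%d discarded by filters), %.4g um/px\n",
              nrow(x$records), x$n_discarded, x$pixel_size_um))
  invisible(x)
}

#' Segment puncta in one channel
#'
#' Convenience wrapper running [yen_threshold()], binarization (pixels
#' strictly above the threshold) and [analyze_particles()] on a single
#' calibrated channel, optionally restricted to a cell mask. This is the
#' per-cropped-cell segmentation route; pass the full field to threshold
#' per field instead.
#'
#' @param image a [calibrated_image()].
#' @param cell_mask optional [region_mask()]; thresholding and analysis are
#'   then restricted to pixels inside the cell.
#' @inheritParams analyze_particles
#' @return A `PunctaSet` (see [analyze_particles()]).
#' @export
segment_puncta <- function(image, cell_mask = NULL,
                           size_range_um2 = c(0, Inf),
                           circularity_range = c(0.5, 1)) {
  stopifnot(inherits(image, "CalibratedImage"))
  px <- image$pixels
  if (!is.null(cell_mask)) {
    .check_congruent(image, cell_mask)
    inside <- .as_pixels(cell_mask)
    thr <- yen_threshold(px[inside])
    fg <- (px > thr) & inside
  } else {
    thr <- yen_threshold(px)
    fg <- px > thr
  }
  out <- analyze_particles(fg, image$pixel_size_um,
                           size_range_um2 = size_range_um2,
                           circularity_range = circularity_range,
                           image = image)
  out$threshold <- thr
  out
}

#' Classify puncta into size bins
#'
#' Tags every object of a `PunctaSet` with exactly one of the bins B1/B2/B3
#' of [size_bins()] and with the independent boolean `large` flag
#' (area >= 0.5 um^2 by default).
#'
#' @param puncta a `PunctaSet` from [analyze_particles()].
#' @param binning a [size_bins()] specification.
#' @return The `PunctaSet` with `bin` (factor, levels B1/B2/B3) and `large`
#'   columns added to `records`.
#' @examples
#' # areas 0.11 -> B1; 0.24 -> B2 (closed edge); 0.50 -> B3 and large
#' @export
classify_size <- function(puncta, binning = size_bins()) {
  stopifnot(inherits(puncta, "PunctaSet"), inherits(binning, "SizeBinning"))
  a <- puncta$records$area_um2
  bin <- ifelse(a < binning$small_max, "B1",
                ifelse(a <= binning$mid_max, "B2", "B3"))
  puncta$records$bin <- factor(bin, levels = c("B1", "B2", "B3"))
  puncta$records$large <- a >= binning$large_min
  puncta
}

#' Render the mask of a (subset of a) PunctaSet
#'
#' @param puncta a `PunctaSet`.
#' @param ids optional object ids to include (default: all).
#' @return A [region_mask()] of kind `"puncta"`.
#' @export
puncta_mask <- function(puncta, ids = NULL) {
  stopifnot(inherits(puncta, "PunctaSet"))
  lm <- puncta$label_map
  keep <- if (is.null(ids)) lm > 0L else matrix(lm %in% ids, nrow(lm), ncol(lm))
  region_mask(keep, kind = "puncta")
}
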