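#' Background-subtracted site intensity
#'
#' Measures the mean intensity of a target channel over a site mask (for
#' example the thresholded lysosome-marker channel) and subtracts the mean
#' of a hand-drawn background region: corrected = mean(sites) - mean(background).
#' Which channel defines the sites is always an explicit caller decision.
#' Negative corrected values (site dimmer than background) are retained and
#' flagged rather than clipped, so condition means stay unbiased.
#'
#' @param target a [calibrated_image()] measured under the masks.
#' @param sites non-empty [region_mask()] of the sites of interest.
#' @param background non-empty [region_mask()] in a dark extracellular region;
#'   must be disjoint from `sites`.
#' @param condition,experiment optional labels carried into the result.
#' @return A one-row data frame: `site_mean_AU`, `background_mean_AU`,
#'   `corrected_AU`, `negative_flag`, `condition`, `experiment`.
#' @export
site_intensity <- function(target, sites, background,
                           condition = NA_character_, experiment = NA_character_) {
  .check_congruent(target, sites)
  .check_congruent(target, background)
  s <- .as_pixels(sites) != 0
  b <- .as_pixels(background) != 0
  if (!any(s)) stop("site mask is empty")
  if (!any(b)) stop("background mask is empty")
  if (any(s & b)) stop("background mask overlaps the site mask")
  px <- .as_pixels(target)
  sm <- mean(px[s]); bm <- mean(px[b])
  data.frame(site_mean_AU = sm, background_mean_AU = bm,
             corrected_AU = sm - bm, negative_flag = sm < bm,
             condition = condition, experiment = experiment,
             stringsAsFactors = FALSE)
}

#' Control-normalized relative intensity
#'
#' Divides each condition's mean corrected intensity by the control
#' condition's mean, so the control maps to exactly 1.0 (the convention in
#' which the vehicle control of each experiment is set to 1).
#'
#' @param values numeric corrected intensities (one per cell).
#' @param condition condition label per value.
#' @param control_condition name of the control condition.
#' @return A data frame with `condition`, `mean_AU`, `relative`, `n`.
#' @export
relative_intensity <- function(values, condition, control_condition) {
  stopifnot(length(values) == length(condition))
  if (!control_condition %in% condition) {
    stop("control condition '", control_condition, "' has no values")
  }
  means <- tapply(values, condition, mean)
  ctrl <- means[[control_condition]]
  if (!is.finite(ctrl) || ctrl <= 0) stop("control mean must be positive")
  data.frame(condition = names(means), mean_AU = as.numeric(means),
             relative = as.numeric(means) / ctrl,
             n = as.integer(table(condition)[names(means)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold overexpression of a tagged marker
#'
#' Each transfected cell's mean intensity divided by the mean over all
#' non-transfected cells for the same marker.
#'
#' @param transfected_cell_means per-cell mean intensities, transfected cells.
#' @param nontransfected_means per-cell mean intensities, non-transfected.
#' @return Numeric vector of per-cell fold overexpression.
#' @export
fold_overexpression <- function(transfected_cell_means, nontransfected_means) {
  if (length(nontransfected_means) < 1L) stop("need at least one non-transfected cell")
  ref <- mean(nontransfected_means)
  if (!is.finite(ref) || ref <= 0) stop("non-transfected mean must be positive")
  transfected_cell_means / ref
}
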