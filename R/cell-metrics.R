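#' Mean puncta size for one cell
#'
#' Arithmetic mean of the calibrated areas of all puncta in the cell (puncta
#' of all sizes are included): total area / total number.
#'
#' @param puncta a `PunctaSet`.
#' @return Mean area in um^2, or `NA` (with a warning) for a cell with no
#'   puncta.
#' @export
mean_puncta_size <- function(puncta) {
  stopifnot(inherits(puncta, "PunctaSet"))
  a <- puncta$records$area_um2
  if (length(a) == 0L) {
    warning("no puncta: mean size undefined")
    return(NA_real_)
  }
  mean(a)
}

#' Percent of cells containing at least one large punctum
#'
#' A cell counts as a "large puncta cell" when it contains at least one
#' punctum of area >= 0.5 um^2 (see [size_bins()]).
#'
#' @param has_large logical vector, one flag per cell, or a data frame with a
#'   `has_large_punctum` column.
#' @return Percent in `[0, 100]`.
#' @export
percent_cells_with_large_puncta <- function(has_large) {
  if (is.data.frame(has_large)) has_large <- has_large$has_large_punctum
  if (length(has_large) == 0L) stop("need at least one cell")
  100 * mean(as.logical(has_large))
}

#' Percent of cells with multiple colocalizing puncta
#'
#' Cells showing `min_count` or more colocalizing puncta divided by the total
#' number of cells analysed, times 100.
#'
#' @param n_coloc integer vector of per-cell colocalizing-puncta counts, or a
#'   data frame with an `n_coloc_puncta` column.
#' @param min_count minimum count for a cell to qualify (default 2,
#'   "two or more").
#' @return Percent in `[0, 100]`.
#' @export
percent_cells_with_multiple_coloc <- function(n_coloc, min_count = 2L) {
  if (is.data.frame(n_coloc)) n_coloc <- n_coloc$n_coloc_puncta
  if (length(n_coloc) == 0L) stop("need at least one cell")
  100 * mean(n_coloc >= min_count)
}

#' Puncta counts per cell
#'
#' @param puncta_by_cell a list of `PunctaSet`, one per cell.
#' @return Integer vector of per-cell puncta counts.
#' @export
puncta_per_cell <- function(puncta_by_cell) {
  vapply(puncta_by_cell, function(p) {
    stopifnot(inherits(p, "PunctaSet"))
    nrow(p$records)
  }, integer(1))
}

#' Summarize one segmented cell
#'
#' Builds the per-cell record used by the reporting stage: puncta count,
#' mean puncta size, the large-punctum flag, and (when a second channel mask
#' is given) the number of puncta colocalizing with that channel.
#'
#' @param puncta a size-classified `PunctaSet` for the cell.
#' @param maskB optional binary mask of a second channel for colocalization
#'   counting.
#' @param cell_id,experiment,condition labels carried into the record.
#' @return One-row data frame (`cell_id`, `experiment`, `condition`,
#'   `n_puncta`, `mean_puncta_size_um2`, `has_large_punctum`,
#'   `n_coloc_puncta`).
#' @export
cell_summary <- function(puncta, maskB = NULL, cell_id = NA, experiment = NA,
                         condition = NA) {
  stopifnot(inherits(puncta, "PunctaSet"))
  if (is.null(puncta$records$large)) puncta <- classify_size(puncta)
  n <- nrow(puncta$records)
  n_coloc <- NA_integer_
  if (!is.null(maskB)) {
    b <- .as_pixels(maskB) != 0
    lm <- puncta$label_map
    n_coloc <- length(unique(lm[b & lm > 0L]))
  }
  data.frame(cell_id = cell_id, experiment = experiment, condition = condition,
             n_puncta = n,
             mean_puncta_size_um2 = if (n > 0) mean(puncta$records$area_um2) else NA_real_,
             has_large_punctum = any(puncta$records$large),
             n_coloc_puncta = n_coloc,
             stringsAsFactors = FALSE)
}
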