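#' Object-overlap percent colocalization
#'
#' Quantifies colocalization of two thresholded channels by object overlap
#' rather than pixel correlation. The intersection image is the pixelwise
#' Boolean AND of the two binary masks; object counts are 8-connected
#' component counts.
#'
#' Two published variants of the statistic are provided:
#' \describe{
#'   \item{`"and_count"` (default)}{percent colocalization of A with B =
#'     count of objects in (A AND B) / count of A objects x 100. Implemented
#'     literally: if one A object produces several intersection fragments the
#'     percent can exceed 100, in which case `over_100` is flagged rather
#'     than capped.}
#'   \item{`"object_hit"`}{A objects colocalized with B / total A objects x
#'     100, i.e. the count of A objects that intersect B at least once over
#'     the A count. Never exceeds 100.}
#' }
#'
#' @param maskA,maskB congruent [region_mask()]s or logical matrices;
#'   the denominator is always channel A.
#' @param mode statistic variant, see Details.
#' @return A list of class `ColocResult`: `count_A`, `count_B`, `count_AND`,
#'   `percent` (`NA` with `undefined = TRUE` when `count_A` is 0), `mode`,
#'   `over_100`.
#' @export
percent_colocalization <- function(maskA, maskB, mode = c("and_count", "object_hit")) {
  mode <- match.arg(mode)
  .check_congruent(maskA, maskB)
  a <- .as_pixels(maskA) != 0
  b <- .as_pixels(maskB) != 0
  labA <- cc_label8(a)
  count_A <- max(labA)
  count_B <- max(cc_label8(b))
  inter <- a & b
  count_AND <- max(cc_label8(inter))
  hits <- if (count_A > 0L) length(unique(labA[inter & labA > 0L])) else 0L
  num <- if (mode == "and_count") count_AND else hits
  undefined <- count_A == 0L
  percent <- if (undefined) NA_real_ else 100 * num / count_A
  structure(list(count_A = count_A, count_B = count_B, count_AND = count_AND,
                 count_A_hit = hits, percent = percent, mode = mode,
                 undefined = undefined,
                 over_100 = isTRUE(percent > 100)),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("ColocResult [%s]: A=%d B=%d AND=%d -> %s%%%s\n",
              x$mode, x$count_A, x$count_B, x$count_AND,
              ifelse(x$undefined, "undefined", sprintf("%.1f", x$percent)),
              ifelse(x$over_100, " (exceeds 100, flagged)", "")))
  invisible(x)
}

#' Size-stratified object colocalization
#'
#' Computes [percent_colocalization()] separately for each size bin of
#' channel-A puncta: the bin's objects are rendered as mask A and compared
#' against the full channel-B mask. Denominators are per bin (the number of
#' A objects in that bin); empty bins yield an undefined percent.
#'
#' @param punctaA a size-classified `PunctaSet` (see [classify_size()]).
#' @param maskB binary mask of the B channel.
#' @param mode passed to [percent_colocalization()].
#' @return A data frame with one row per bin: `bin`, `n_A`, `count_AND`,
#'   `percent` (NA for empty bins).
#' @export
size_stratified_colocalization <- function(punctaA, maskB,
                                           mode = c("and_count", "object_hit")) {
  mode <- match.arg(mode)
  stopifnot(inherits(punctaA, "PunctaSet"))
  if (is.null(punctaA$records$bin)) punctaA <- classify_size(punctaA)
  .check_congruent(punctaA$label_map, maskB)
  bins <- levels(punctaA$records$bin)
  out <- lapply(bins, function(bn) {
    ids <- punctaA$records$id[punctaA$records$bin == bn]
    if (length(ids) == 0L) {
      return(data.frame(bin = bn, n_A = 0L, count_AND = 0L, percent = NA_real_))
    }
    res <- percent_colocalization(puncta_mask(punctaA, ids), maskB, mode = mode)
    data.frame(bin = bn, n_A = res$count_A, count_AND = res$count_AND,
               percent = res$percent)
  })
  do.call(rbind, out)
}

#' Area-overlap fraction (lysosomal delivery estimate)
#'
#' Fraction of channel-A area that overlaps channel B, by pixel area:
#' `|A AND B| / |A|`. Used to estimate the fraction of cargo delivered to
#' lysosomes by dividing the cargo area overlapping the lysosome marker by
#' the total cargo area in the cell.
#'
#' @param maskA,maskB congruent binary masks; A must be non-empty.
#' @return A single fraction in `[0, 1]`.
#' @export
area_overlap_fraction <- function(maskA, maskB) {
  .check_congruent(maskA, maskB)
  a <- .as_pixels(maskA) != 0
  b <- .as_pixels(maskB) != 0
  na <- sum(a)
  if (na == 0L) stop("mask A is empty: overlap fraction undefined")
  sum(a & b) / na
}
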