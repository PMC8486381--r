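#' Analysis configuration
#'
#' Bundles the fixed analysis parameters of the workflow. Every default is
#' the value the quantification protocol prescribes (size bins, circularity
#' 0.5-1, the Methods colocalization formula); any override is recorded in
#' the `overrides` field so a run log can show it.
#'
#' @param pixel_size_um calibration applied when images carry none.
#' @param binning a [size_bins()] object.
#' @param circularity_range particle-analysis circularity filter.
#' @param coloc_mode `"and_count"` (Methods formula) or `"object_hit"`.
#' @param max_disp_um,frame_interval_s tracking parameters.
#' @param frap_schedule FRAP acquisition time stamps.
#' @param seed integer seed for any stochastic stage.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(pixel_size_um = 0.08,
                            binning = size_bins(),
                            circularity_range = c(0.5, 1),
                            coloc_mode = c("and_count", "object_hit"),
                            max_disp_um = 1, frame_interval_s = NULL,
                            frap_schedule = default_frap_schedule(),
                            seed = 1L) {
  coloc_mode <- match.arg(coloc_mode)
  supplied <- names(as.list(match.call())[-1L])
  structure(list(pixel_size_um = pixel_size_um, binning = binning,
                 circularity_range = circularity_range,
                 coloc_mode = coloc_mode, max_disp_um = max_disp_um,
                 frame_interval_s = frame_interval_s,
                 frap_schedule = frap_schedule, seed = as.integer(seed),
                 overrides = supplied),
            class = "PipelineConfig")
}

#' Run the puncta-morphology pipeline over a manifest of cells
#'
#' Each manifest item is one cell: a target-channel image (in memory or a
#' TIFF path), an optional second-channel image for colocalization, an
#' optional cell mask, and its condition/experiment tags. The pipeline
#' segments the target channel (Yen threshold + particle analysis with the
#' configured filters), classifies sizes, summarizes each cell, aggregates
#' per condition with the experiment as the unit of replication, and runs
#' Student's unpaired t-tests between all condition pairs on the per-
#' experiment percentages of cells with large puncta. Items that fail are
#' reported in the log and skipped; the run continues for valid items.
#'
#' @param manifest a list of items; each a list with fields `image`
#'   (CalibratedImage or TIFF path), optional `image_b`, optional
#'   `cell_mask`, and `condition`, `experiment`, `cell_id` tags.
#' @param config a [pipeline_config()].
#' @return A list of class `PipelineResult`: `cells` (per-cell data frame),
#'   `summaries` (per-condition data frame of the large-puncta percentage),
#'   `tests` (pairwise t-test table), `config`, `log` (character).
#' @export
run_pipeline <- function(manifest, config = pipeline_config()) {
  if (length(manifest) == 0L) stop("empty manifest")
  log <- character(0)
  cells <- list()
  for (i in seq_along(manifest)) {
    item <- manifest[[i]]
    res <- tryCatch({
      img <- item$image
      if (is.character(img)) img <- read_image(img, config$pixel_size_um)[[1L]]
      mask <- item$cell_mask
      seg <- segment_puncta(img, cell_mask = mask,
                            circularity_range = config$circularity_range)
      seg <- classify_size(seg, config$binning)
      maskB <- NULL
      if (!is.null(item$image_b)) {
        imgB <- item$image_b
        if (is.character(imgB)) imgB <- read_image(imgB, config$pixel_size_um)[[1L]]
        segB <- segment_puncta(imgB, cell_mask = mask,
                               circularity_range = config$circularity_range)
        maskB <- puncta_mask(segB)
      }
      cell_summary(seg, maskB = maskB,
                   cell_id = if (is.null(item$cell_id)) i else item$cell_id,
                   experiment = item$experiment, condition = item$condition)
    }, error = function(e) {
      log <<- c(log, sprintf("item %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) cells[[length(cells) + 1L]] <- res
  }
  if (length(cells) == 0L) stop("no manifest item could be processed")
  cells <- do.call(rbind, cells)
  conds <- unique(cells$condition)
  summaries <- list(); pct_by_cond <- list()
  for (cd in conds) {
    sub <- cells[cells$condition == cd, ]
    pct <- tapply(as.numeric(sub$has_large_punctum), sub$experiment, mean) * 100
    agg <- aggregate_experiments(as.numeric(sub$has_large_punctum) * 100,
                                 sub$experiment, condition = cd)
    pct_by_cond[[cd]] <- pct
    summaries[[cd]] <- data.frame(condition = cd,
                                  percent_large = agg$mean, sem = agg$sem,
                                  n_experiments = agg$n_experiments,
                                  n_cells = nrow(sub))
  }
  tests <- NULL
  if (length(conds) >= 2L) {
    pairs <- utils::combn(conds, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pct_by_cond[[pairs[1L, k]]]; b <- pct_by_cond[[pairs[2L, k]]]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      tt <- unpaired_t_test(a, b)
      data.frame(condition_A = pairs[1L, k], condition_B = pairs[2L, k],
                 mean_A = tt$mean_A, mean_B = tt$mean_B, t = tt$t, df = tt$df,
                 p = tt$p, stars = tt$stars)
    }))
  }
  structure(list(cells = cells, summaries = do.call(rbind, summaries),
                 tests = tests, config = config, log = log),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult:", nrow(x$cells), "cells\n")
  print(x$summaries)
  if (!is.null(x$tests)) print(x$tests)
  if (length(x$log)) cat(length(x$log), "items skipped (see $log)\n")
  invisible(x)
}

# one simulated cell for the demo experiment: a small field with a few
# small puncta and, with probability p_large, one large (>= 0.5 um^2) punctum
.demo_cell <- function(seed, p_large, image_shape = c(96L, 96L)) {
  set.seed(seed)
  has_large <- stats::runif(1) < p_large
  areas <- c(stats::runif(2, 0.04, 0.10), stats::runif(1, 0.135, 0.225))
  if (has_large) areas <- c(areas, stats::runif(1, 0.6, 1.0))
  spec <- scene_spec(image_shape = image_shape, channels = "target",
                     puncta_areas = list(areas),
                     n_tubule_nodes = 8L, n_sheets = 1L,
                     sheet_axis_px = c(8, 14), seed = seed)
  sc <- make_scene(spec)
  seg <- classify_size(segment_puncta(sc$images[[1L]], sc$cell_mask))
  list(truth_large = has_large, measured_large = any(seg$records$large),
       n_puncta = nrow(seg$records))
}

#' End-to-end demonstration experiment on synthetic cells
#'
#' Simulates the headline contrast of the workflow: control cells form a
#' large punctum with low probability while knockout-like cells do so with
#' high probability. Each simulated cell is rendered as an image, segmented
#' with the full pipeline (Yen threshold, particle analysis, size
#' classification), and scored for large puncta; per-experiment percentages
#' are aggregated and compared with Student's unpaired t-test. Defaults
#' mirror the reported contrast of roughly 15% of control versus 76% of
#' tubule-network-deficient cells containing large puncta.
#'
#' @param seed integer seed.
#' @param p_large_control,p_large_ko per-cell probability of a large
#'   punctum in the two conditions.
#' @param n_experiments independent experiments per condition.
#' @param cells_per_experiment cells per experiment.
#' @return A list: `cells` (per-cell data frame), `summary` (per-condition
#'   mean +- SEM of the large-puncta percentage), `t_test`, `stars`.
#' @export
demo_experiment <- function(seed = 1L, p_large_control = 0.15,
                            p_large_ko = 0.76, n_experiments = 3L,
                            cells_per_experiment = 30L) {
  conds <- c(control = p_large_control, ko = p_large_ko)
  rows <- list()
  k <- 0L
  for (cd in names(conds)) {
    for (e in seq_len(n_experiments)) {
      for (cl in seq_len(cells_per_experiment)) {
        k <- k + 1L
        cell <- .demo_cell(.derived_seed(seed, k), conds[[cd]])
        rows[[k]] <- data.frame(condition = cd, experiment = paste0(cd, "_e", e),
                                cell = cl, truth_large = cell$truth_large,
                                has_large_punctum = cell$measured_large,
                                n_puncta = cell$n_puncta)
      }
    }
  }
  cells <- do.call(rbind, rows)
  pct <- lapply(names(conds), function(cd) {
    sub <- cells[cells$condition == cd, ]
    tapply(as.numeric(sub$has_large_punctum), sub$experiment, mean) * 100
  })
  names(pct) <- names(conds)
  summary <- do.call(rbind, lapply(names(conds), function(cd) {
    agg <- aggregate_experiments(
      as.numeric(cells$has_large_punctum[cells$condition == cd]) * 100,
      cells$experiment[cells$condition == cd], condition = cd)
    data.frame(condition = cd, percent_large = agg$mean, sem = agg$sem,
               n_experiments = agg$n_experiments)
  }))
  tt <- unpaired_t_test(pct$control, pct$ko)
  list(cells = cells, summary = summary, percent_by_experiment = pct,
       t_test = tt, stars = tt$stars)
}
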