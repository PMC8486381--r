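#' Aggregate per-cell values to experiment-level statistics
#'
#' The unit of replication is the independent experiment, not the cell:
#' per-cell values are first averaged within each experiment, then the
#' cross-experiment mean and SEM (sd / sqrt(n experiments)) are computed.
#' With a single experiment the SEM is undefined and flagged `NA`.
#'
#' @param values per-cell values.
#' @param experiment experiment id per value.
#' @param condition optional condition label (single value) carried through.
#' @return A list of class `ConditionSummary`: `condition`,
#'   `experiment_means` (named), `mean`, `sem`, `n_experiments`.
#' @export
aggregate_experiments <- function(values, experiment, condition = NA_character_) {
  stopifnot(length(values) == length(experiment))
  if (anyNA(experiment)) stop("every value must be tagged with an experiment id")
  em <- tapply(values, experiment, mean)
  em <- stats::setNames(as.numeric(em), names(em))
  n <- length(em)
  structure(list(condition = condition,
                 experiment_means = em,
                 mean = mean(em),
                 sem = if (n >= 2L) stats::sd(em) / sqrt(n) else NA_real_,
                 n_experiments = n),
            class = "ConditionSummary")
}

#' @export
print.ConditionSummary <- function(x, ...) {
  cat(sprintf("ConditionSummary '%s': mean %.4g, SEM %s, n = %d experiments\n",
              x$condition, x$mean,
              ifelse(is.na(x$sem), "undefined", sprintf("%.4g", x$sem)),
              x$n_experiments))
  invisible(x)
}

#' Two-sample Student's t-test (equal variance)
#'
#' Classical equal-variance unpaired t-test with `nA + nB - 2` degrees of
#' freedom and a two-sided p-value, the test reported throughout this
#' workflow's figure statistics. Welch's correction is available as an
#' option. Degenerate inputs with zero pooled variance are handled by
#' convention: equal means give p = 1, unequal means p = 0 (flagged).
#'
#' @param groupA,groupB numeric vectors with at least 2 values each
#'   (typically per-experiment means).
#' @param var_equal use the pooled-variance Student form (default `TRUE`).
#' @return A list: `t`, `p`, `df`, `mean_A`, `mean_B`, `stars`,
#'   `degenerate` (zero-variance flag).
#' @export
unpaired_t_test <- function(groupA, groupB, var_equal = TRUE) {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
    eq <- isTRUE(all.equal(mean(groupA), mean(groupB)))
    p <- if (eq) 1 else 0
    return(list(t = if (eq) 0 else Inf * sign(mean(groupA) - mean(groupB)),
                p = p, df = length(groupA) + length(groupB) - 2L,
                mean_A = mean(groupA), mean_B = mean(groupB),
                stars = significance_stars(p), degenerate = TRUE))
  }
  ht <- stats::t.test(groupA, groupB, var.equal = var_equal)
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter),
       mean_A = mean(groupA), mean_B = mean(groupB),
       stars = significance_stars(unname(ht$p.value)), degenerate = FALSE)
}

#' Significance star labels
#'
#' `NS` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001.
#'
#' @param p p-value(s).
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}

#' Average paired scores from two independent observers
#'
#' Element-wise mean of two observers' per-experiment percentages, the
#' downstream step of blind two-observer scoring.
#'
#' @param scoresA,scoresB equal-length numeric vectors.
#' @return Per-experiment averaged scores.
#' @export
two_observer_average <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB)) stop("observer score lengths differ")
  (scoresA + scoresB) / 2
}
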