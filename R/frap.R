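#' Default FRAP acquisition schedule
#'
#' Six pre-bleach frames at two frames per second, post-bleach frames
#' continuously (0.5 s cadence) for 30 s, then at 2 s intervals for a further
#' two minutes. The bleach defines t = 0; the first post-bleach frame sits
#' half a frame interval after it.
#'
#' @return Numeric vector of time stamps in seconds (negative = pre-bleach).
#' @export
default_frap_schedule <- function() {
  pre <- seq(-3, -0.5, by = 0.5)
  fast <- seq(0.25, 30.25, by = 0.5)
  slow <- seq(32.25, 150.25, by = 2)
  c(pre, fast, slow)
}

#' FRAP trace container
#'
#' Time-stamped mean intensities of the bleached ROI, the whole cell, and a
#' background region, with the bleach at t = 0.
#'
#' @param t_s strictly increasing time stamps (seconds; negative before the
#'   bleach).
#' @param bleach,whole_cell,background mean ROI intensities (AU) per frame.
#' @return Object of class `FrapTrace` (a data frame).
#' @export
frap_trace <- function(t_s, bleach, whole_cell, background) {
  stopifnot(length(t_s) == length(bleach),
            length(t_s) == length(whole_cell),
            length(t_s) == length(background))
  if (any(diff(t_s) <= 0)) stop("time stamps must be strictly increasing")
  if (sum(t_s < 0) < 3L) stop("need at least 3 pre-bleach samples")
  if (sum(t_s >= 0) < 5L) stop("need at least 5 post-bleach samples")
  structure(data.frame(t_s = t_s, bleach = bleach, whole_cell = whole_cell,
                       background = background),
            class = c("FrapTrace", "data.frame"))
}

#' Double (or single) normalization of a FRAP trace
#'
#' Double normalization corrects the bleach-ROI trace for acquisition
#' (monitor) bleaching using the whole-cell signal:
#' \deqn{N(t) = \frac{W_{pre}}{W(t) - bg(t)} \times \frac{B(t) - bg(t)}{B_{pre}}}
#' where \eqn{W_{pre}} and \eqn{B_{pre}} are the background-subtracted
#' pre-bleach means of the whole-cell and bleach ROIs. The pre-bleach mean of
#' the normalized trace is 1 by construction, and the result is invariant to
#' rescaling the raw channels. Single normalization
#' (\eqn{(B - bg)/B_{pre}}) is available for acquisitions without a usable
#' whole-cell channel.
#'
#' @param trace a [frap_trace()].
#' @param method `"double"` (default) or `"single"`.
#' @return The trace with a `norm` column appended.
#' @export
normalize_frap <- function(trace, method = c("double", "single")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "FrapTrace"))
  pre <- trace$t_s < 0
  B <- trace$bleach - trace$background
  W <- trace$whole_cell - trace$background
  B_pre <- mean(B[pre])
  W_pre <- mean(W[pre])
  if (B_pre <= 0) stop("pre-bleach bleach-ROI signal must exceed background")
  if (method == "double") {
    if (any(W <= 0)) stop("whole-cell signal must exceed background at every sample")
    trace$norm <- (W_pre / W) * (B / B_pre)
  } else {
    trace$norm <- B / B_pre
  }
  trace
}

#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of the post-bleach samples of a normalized trace to
#' \deqn{N(t) = b_0 + (plateau - b_0)(1 - e^{-kt}), \quad t \ge 0}
#' returning the mobile fraction `M = (plateau - b0) / (1 - b0)` (pre-bleach
#' level 1), the recovery half-time `ln(2)/k`, and the recovery percentage
#' `100 * plateau` (the plateau relative to the pre-bleach level). Starting
#' values come from the data: `b0` from the first post-bleach point, the
#' plateau from the final 10% of samples, and `k` from the time at which the
#' trace first crosses the recovery midpoint. A flat trace (no measurable
#' recovery) yields `mobile_fraction = 0` with an undefined half-time flag.
#'
#' @param trace a normalized trace from [normalize_frap()] (or any data frame
#'   with `t_s` and `norm`).
#' @return A list of class `FrapFit`: `mobile_fraction`, `half_time_s`,
#'   `rate_per_s`, `bleach_depth`, `plateau`, `recovery_percent`,
#'   `resid_norm`, `half_time_defined`.
#' @export
fit_frap <- function(trace) {
  tr <- as.data.frame(trace)
  if (is.null(tr$norm)) stop("trace has no 'norm' column; run normalize_frap() first")
  post <- tr[tr$t_s >= 0, , drop = FALSE]
  if (nrow(post) < 5L) stop("need at least 5 post-bleach samples")
  t <- post$t_s; y <- post$norm
  b0_init <- y[1L]
  n_tail <- max(3L, ceiling(0.1 * length(y)))
  plat_init <- mean(utils::tail(y, n_tail))
  if (plat_init - b0_init < 1e-8 && stats::sd(y) < 1e-8) {
    # perfectly flat: immobile, rate unidentifiable
    return(structure(list(mobile_fraction = 0, half_time_s = NA_real_,
                          rate_per_s = NA_real_, bleach_depth = mean(y),
                          plateau = mean(y), recovery_percent = 100 * mean(y),
                          resid_norm = 0, half_time_defined = FALSE),
                     class = "FrapFit"))
  }
  mid <- (b0_init + plat_init) / 2
  t_mid <- suppressWarnings(min(t[y >= mid]))
  k_init <- if (is.finite(t_mid) && t_mid > 0) log(2) / t_mid else 0.1
  fit <- try(minpack.lm::nlsLM(
    y ~ b0 + (plateau - b0) * (1 - exp(-k * t)),
    start = list(b0 = b0_init, plateau = plat_init, k = k_init),
    lower = c(b0 = 0, plateau = 0, k = 1e-6),
    upper = c(b0 = 1.5, plateau = 2, k = 100),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) stop("FRAP fit did not converge")
  cf <- stats::coef(fit)
  b0 <- unname(cf["b0"]); plateau <- unname(cf["plateau"]); k <- unname(cf["k"])
  defined <- k > 1e-5 && (plateau - b0) > 1e-6
  M <- if (b0 < 1) (plateau - b0) / (1 - b0) else NA_real_
  structure(list(mobile_fraction = max(0, min(1, M)),
                 half_time_s = if (defined) log(2) / k else NA_real_,
                 rate_per_s = k, bleach_depth = b0, plateau = plateau,
                 recovery_percent = 100 * plateau,
                 resid_norm = sqrt(sum(stats::resid(fit)^2)),
                 half_time_defined = defined),
            class = "FrapFit")
}

#' @export
print.FrapFit <- function(x, ...) {
  cat(sprintf(
    "FrapFit: mobile fraction %.3f, half-time %s s, plateau %.3f (recovery %.1f%%)\n",
    x$mobile_fraction,
    ifelse(x$half_time_defined, sprintf("%.2f", x$half_time_s), "undefined"),
    x$plateau, x$recovery_percent))
  invisible(x)
}
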