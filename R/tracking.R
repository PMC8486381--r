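#' Link puncta detections across time-lapse frames
#'
#' Frame-to-frame nearest-neighbour linking: for each consecutive frame pair,
#' candidate links are sorted by distance and assigned greedily one-to-one,
#' rejecting links longer than `max_disp_um`. Unmatched detections end their
#' track or start a new one; tracks are never bridged across a missed frame
#' (no gap closing). Greedy distance-ascending assignment is reproducible and
#' adequate at the puncta densities this workflow targets.
#'
#' @param frames list of per-frame `PunctaSet`s (or data frames with
#'   `centroid_x_um` / `centroid_y_um` columns), in time order.
#' @param max_disp_um maximum allowed displacement between frames (um).
#' @param frame_interval_s time between consecutive frames (seconds). The
#'   acquisition interval is a required input; it is never guessed.
#' @return A data frame of track samples: `track`, `frame`, `t_s`, `x_um`,
#'   `y_um`, `area_um2`.
#' @export
link_puncta <- function(frames, max_disp_um, frame_interval_s) {
  stopifnot(length(frames) >= 2L, max_disp_um > 0, frame_interval_s > 0)
  dets <- lapply(frames, function(f) {
    r <- if (inherits(f, "PunctaSet")) f$records else as.data.frame(f)
    if (nrow(r) == 0L) {
      return(data.frame(x = numeric(0), y = numeric(0), area = numeric(0)))
    }
    data.frame(x = r$centroid_x_um, y = r$centroid_y_um,
               area = if ("area_um2" %in% names(r)) r$area_um2 else NA_real_)
  })
  n_frames <- length(dets)
  track_of <- lapply(dets, function(d) rep(NA_integer_, nrow(d)))
  next_track <- 0L
  for (i in seq_len(nrow(dets[[1]]))) {
    next_track <- next_track + 1L
    track_of[[1]][i] <- next_track
  }
  for (f in seq_len(n_frames - 1L)) {
    a <- dets[[f]]; b <- dets[[f + 1L]]
    if (nrow(a) > 0L && nrow(b) > 0L) {
      d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
      cand <- which(d <= max_disp_um, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
        for (k in seq_len(nrow(cand))) {
          ia <- cand[k, 1L]; ib <- cand[k, 2L]
          if (used_a[ia] || used_b[ib]) next
          used_a[ia] <- TRUE; used_b[ib] <- TRUE
          track_of[[f + 1L]][ib] <- track_of[[f]][ia]
        }
      }
    }
    for (i in seq_len(nrow(b))) {
      if (is.na(track_of[[f + 1L]][i])) {
        next_track <- next_track + 1L
        track_of[[f + 1L]][i] <- next_track
      }
    }
  }
  out <- do.call(rbind, lapply(seq_len(n_frames), function(f) {
    d <- dets[[f]]
    if (nrow(d) == 0L) return(NULL)
    data.frame(track = track_of[[f]], frame = f,
               t_s = (f - 1L) * frame_interval_s,
               x_um = d$x, y_um = d$y, area_um2 = d$area)
  }))
  out[order(out$track, out$frame), , drop = FALSE]
}

#' Total-path-length track velocity
#'
#' The velocity of a punctum is the calibrated total (not net) linear
#' distance of travel per unit time of the recording: the sum of consecutive
#' Euclidean step lengths divided by the elapsed time from first to last
#' sample. A punctum that loops back to its start therefore still has a
#' positive velocity; the `"net"` method (net displacement / time) is
#' provided for comparison and is never larger.
#'
#' @param track data frame with `t_s`, `x_um`, `y_um` columns (one track),
#'   at least two samples, strictly increasing time stamps.
#' @param method `"total_path"` (the definition used throughout) or `"net"`.
#' @return Velocity in um/s.
#' @export
track_velocity <- function(track, method = c("total_path", "net")) {
  method <- match.arg(method)
  track <- as.data.frame(track)
  stopifnot(nrow(track) >= 2L)
  t <- track$t_s
  if (any(diff(t) <= 0)) stop("time stamps must be strictly increasing")
  dt <- t[length(t)] - t[1L]
  if (method == "total_path") {
    steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
    sum(steps) / dt
  } else {
    sqrt((track$x_um[nrow(track)] - track$x_um[1L])^2 +
           (track$y_um[nrow(track)] - track$y_um[1L])^2) / dt
  }
}

#' Velocities of all tracks in a linking result
#'
#' @param tracks output of [link_puncta()].
#' @param min_samples minimum samples for a track to receive a velocity.
#' @param method passed to [track_velocity()].
#' @return Data frame `track`, `n_samples`, `velocity_um_s`, `mean_area_um2`.
#' @export
track_velocities <- function(tracks, min_samples = 2L,
                             method = c("total_path", "net")) {
  method <- match.arg(method)
  sp <- split(tracks, tracks$track)
  rows <- lapply(sp, function(tr) {
    if (nrow(tr) < min_samples) return(NULL)
    data.frame(track = tr$track[1L], n_samples = nrow(tr),
               velocity_um_s = track_velocity(tr, method = method),
               mean_area_um2 = mean(tr$area_um2))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(track = integer(0), n_samples = integer(0),
                      velocity_um_s = numeric(0), mean_area_um2 = numeric(0))
  }
  rownames(out) <- NULL
  out
}
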