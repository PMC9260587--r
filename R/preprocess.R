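# Track preprocessing: gap interpolation, smoothing, confidence-based QC.

#' Fill short detection gaps by linear interpolation
#'
#' Tracking output loses the animal for occasional frames. Internal gaps of at
#' most `max_gap` consecutive missing frames are filled by linear
#' interpolation of `x` and `y` between the flanking detections; filled points
#' carry `confidence = NA` and `interpolated = TRUE`. Longer gaps are left
#' unfilled, and leading/trailing gaps are never extrapolated — positions
#' before the first or after the last detection are unknowable from the data.
#'
#' Originally detected points are never altered.
#'
#' @param trial A [tracked_trial()].
#' @param max_gap Maximum internal gap length, in frames, to fill.
#'   `max_gap = 0` disables filling.
#' @return A [tracked_trial()] with gaps filled.
#' @export
interpolate_gaps <- function(trial, max_gap = 5) {
  stopifnot(inherits(trial, "tracked_trial"),
            is.numeric(max_gap), length(max_gap) == 1, max_gap >= 0)
  tr <- trial$track
  if (nrow(tr) < 2 || max_gap == 0) return(trial)
  pieces <- vector("list", 2L * nrow(tr) - 1L)
  pieces[[1]] <- tr[1, ]
  for (i in seq_len(nrow(tr) - 1)) {
    gap <- tr$frame[i + 1] - tr$frame[i] - 1L
    if (gap >= 1 && gap <= max_gap) {
      frames <- (tr$frame[i] + 1L):(tr$frame[i + 1] - 1L)
      w <- (frames - tr$frame[i]) / (tr$frame[i + 1] - tr$frame[i])
      pieces[[2 * i]] <- tibble::tibble(
        frame = frames,
        t = frames / trial$arena$fps,
        x = tr$x[i] + w * (tr$x[i + 1] - tr$x[i]),
        y = tr$y[i] + w * (tr$y[i + 1] - tr$y[i]),
        confidence = NA_real_,
        interpolated = TRUE
      )
    }
    pieces[[2 * i + 1]] <- tr[i + 1, ]
  }
  out <- trial
  out$track <- dplyr::bind_rows(pieces)
  out
}

#' Smooth a track with a centered moving average
#'
#' Applies a centered moving average of odd width `window` to `x` and `y`,
#' truncating the window where it would overhang the track ends (the first
#' and last points are averaged over the part of the window that exists).
#' `window = 1` is the identity. The average is taken over consecutive track
#' rows; run [interpolate_gaps()] first so that rows are (near-)contiguous in
#' time.
#'
#' @param trial A [tracked_trial()].
#' @param window Odd integer window width in frames.
#' @return The smoothed [tracked_trial()].
#' @export
smooth_track <- function(trial, window = 5) {
  stopifnot(inherits(trial, "tracked_trial"),
            is.numeric(window), length(window) == 1, window >= 1)
  if (window %% 2 == 0) stop("smoothing window must be odd", call. = FALSE)
  tr <- trial$track
  n <- nrow(tr)
  if (n == 0 || window == 1) return(trial)
  half <- (window - 1) / 2
  # cumulative sums give the truncated centered mean in O(n)
  csx <- cumsum(c(0, tr$x)); csy <- cumsum(c(0, tr$y))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  out <- trial
  out$track$x <- (csx[hi + 1] - csx[lo]) / (hi - lo + 1)
  out$track$y <- (csy[hi + 1] - csy[lo]) / (hi - lo + 1)
  out
}

#' Mean detection confidence of a trial
#'
#' The mean detection certainty across all nominal video frames of the trial
#' (`round(fps * trial_duration)` frames). Frames at which the animal was not
#' detected — absent from the track, gap-filled, or detected with unknown
#' certainty — contribute confidence 0, so tracking loss is penalized
#' consistently. Compute this on raw trials, before gap interpolation.
#'
#' @param trial A [tracked_trial()].
#' @return Mean confidence, a fraction in `[0, 1]`.
#' @export
mean_confidence <- function(trial) {
  stopifnot(inherits(trial, "tracked_trial"))
  tr <- trial$track
  if (nrow(tr) == 0) stop("mean_confidence is undefined for an empty track",
                          call. = FALSE)
  total <- max(n_frames(trial$arena), max(tr$frame) + 1L)
  conf <- tr$confidence
  conf[is.na(conf) | tr$interpolated] <- 0
  sum(conf) / total
}

#' Quality-control filter on mean detection confidence
#'
#' Retains trials whose mean detection confidence exceeds `threshold`
#' (strictly), mirroring the usual "average certainty above 70%" inclusion
#' criterion; excluded trials are returned with a human-readable reason for
#' the run report.
#'
#' @param trials A list of [tracked_trial()] objects.
#' @param threshold Retention threshold in `[0, 1]`. Default 0.70.
#' @return A list with elements `retained` (list of trials), `excluded`
#'   (list of trials), and `log` — a tibble with columns `trial_id`,
#'   `mean_confidence`, `retained`, `reason`.
#' @export
qc_filter_trials <- function(trials, threshold = 0.70) {
  stopifnot(is.list(trials), is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 1)
  conf <- purrr::map_dbl(trials, function(tr) {
    if (nrow(tr$track) == 0) 0 else mean_confidence(tr)
  })
  keep <- conf > threshold
  log <- tibble::tibble(
    trial_id = purrr::map_chr(trials, "trial_id"),
    mean_confidence = conf,
    retained = keep,
    reason = ifelse(keep, NA_character_,
                    sprintf("mean confidence %.3f <= threshold %.2f",
                            conf, threshold))
  )
  list(retained = trials[keep], excluded = trials[!keep], log = log)
}

#' Preprocess a list of trials
#'
#' Convenience wrapper applying [interpolate_gaps()] then [smooth_track()]
#' to every trial, in that order.
#'
#' @param trials A list of [tracked_trial()] objects.
#' @param max_gap Passed to [interpolate_gaps()].
#' @param window Passed to [smooth_track()].
#' @return The list of preprocessed trials.
#' @export
preprocess_trials <- function(trials, max_gap = 5, window = 5) {
  purrr::map(trials, function(tr) {
    smooth_track(interpolate_gaps(tr, max_gap = max_gap), window = window)
  })
}
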