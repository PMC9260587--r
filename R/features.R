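# The eleven per-trial movement features and their geometric primitives.
#
# Feature conventions: S is the first track point, A the first point in
# proximity to the stranger ("approach point"), E the last track point.
# "Contact"/"proximity" means lying within contact_threshold of the circle
# occupied by the stranger (boundary inclusive).

#' Canonical feature names, in fixed column order
#'
#' The eleven movement features computed per trial, in the order used by
#' [build_feature_table()] and all downstream reports.
#'
#' @return Character vector of length 11.
#' @export
feature_names <- function() {
  c("time_until_approach", "duration_of_approach", "speed_of_first_approach",
    "trajectory_length", "trajectory_length_until_first_approach",
    "area", "intensity_of_use", "total_contact",
    "straightness", "straightness_until_first_approach", "contact_ratio")
}

dist_to_stranger <- function(x, y, arena) {
  sqrt((x - arena$stranger_center[1])^2 + (y - arena$stranger_center[2])^2)
}

#' Is a point in proximity to the stranger?
#'
#' `TRUE` when the euclidean distance from the point to the stranger's center
#' is at most `stranger_radius + contact_threshold`. The boundary is
#' inclusive, so a point exactly on the outer contact circle is in contact.
#'
#' @param x,y Numeric vectors of pixel coordinates (recycled together).
#' @param arena An [arena_config()].
#' @return Logical vector.
#' @export
in_contact <- function(x, y, arena) {
  stopifnot(inherits(arena, "arena_config"))
  dist_to_stranger(x, y, arena) <= arena$stranger_radius + arena$contact_threshold
}

#' Detect approach events in a trial
#'
#' Identifies the approach point `A` — the earliest track point in proximity
#' to the stranger — and the approach onset: the latest time before first
#' contact at which the animal was still outside an outer band of width
#' `onset_band` beyond the contact circle (or the trial start, if it never
#' was). The segment onset..contact is "the first approach"; its duration and
#' traversed path define the approach-speed features.
#'
#' @param trial A preprocessed [tracked_trial()].
#' @param onset_band Width in pixels of the outer band defining approach
#'   onset. `NULL` (default) uses `2 * stranger_radius`; `Inf` makes the
#'   approach start at the trial start.
#' @return An object of class `approach_events`: a list with `approached`
#'   (flag), `S`, `A`, `E` (xy pairs; `A` is `NULL` when never approached),
#'   `t_A`, `t_onset` (seconds; `NA` when never approached), and the row
#'   indices `i_A`, `i_onset` used internally.
#' @export
detect_approach_events <- function(trial, onset_band = NULL) {
  stopifnot(inherits(trial, "tracked_trial"))
  tr <- trial$track
  if (nrow(tr) == 0) {
    stop("approach events are undefined for an empty track", call. = FALSE)
  }
  arena <- trial$arena
  if (is.null(onset_band)) onset_band <- 2 * arena$stranger_radius
  stopifnot(is.numeric(onset_band), length(onset_band) == 1, onset_band >= 0)
  d <- dist_to_stranger(tr$x, tr$y, arena)
  contact_r <- arena$stranger_radius + arena$contact_threshold
  contact <- d <= contact_r
  S <- c(tr$x[1], tr$y[1])
  E <- c(tr$x[nrow(tr)], tr$y[nrow(tr)])
  if (!any(contact)) {
    return(structure(
      list(approached = FALSE, S = S, A = NULL, E = E,
           t_A = NA_real_, t_onset = NA_real_,
           i_A = NA_integer_, i_onset = NA_integer_),
      class = "approach_events"
    ))
  }
  i_A <- which(contact)[1]
  outside <- which(seq_along(d) < i_A & d > contact_r + onset_band)
  i_onset <- if (length(outside) > 0) max(outside) else 1L
  structure(
    list(approached = TRUE, S = S, A = c(tr$x[i_A], tr$y[i_A]), E = E,
         t_A = tr$t[i_A], t_onset = if (i_A == 1) 0 else tr$t[i_onset],
         i_A = as.integer(i_A), i_onset = as.integer(i_onset)),
    class = "approach_events"
  )
}

get_xy <- function(track) {
  if (inherits(track, "tracked_trial")) track <- track$track
  if (is.matrix(track)) track <- tibble::tibble(x = track[, 1], y = track[, 2])
  stopifnot(all(c("x", "y") %in% names(track)))
  track
}

#' Path length along a track segment
#'
#' Sum of consecutive euclidean segment lengths between track rows `i` and
#' `j` (1-based, inclusive). Zero when `i == j`. Additive over concatenated
#' ranges: `path_length(tr, i, k) + path_length(tr, k, j) ==
#' path_length(tr, i, j)`.
#'
#' @param track A [tracked_trial()], a data frame with `x`/`y` columns, or a
#'   two-column matrix.
#' @param i,j Row indices, `1 <= i <= j <= n`.
#' @return Length in pixels.
#' @export
path_length <- function(track, i = 1, j = NULL) {
  tr <- get_xy(track)
  n <- nrow(tr)
  if (is.null(j)) j <- n
  if (i < 1 || j > n || i > j) {
    stop("path_length indices out of range (i=", i, ", j=", j, ", n=", n, ")",
         call. = FALSE)
  }
  if (i == j) return(0)
  idx <- i:j
  sum(sqrt(diff(tr$x[idx])^2 + diff(tr$y[idx])^2))
}

#' Area of the convex hull of a track
#'
#' The area covered by the animal, approximated as the convex hull of all its
#' positions (shoelace formula on the hull vertices). Degenerate tracks —
#' fewer than three distinct points, or all points collinear — have area 0.
#'
#' @inheritParams path_length
#' @return Area in squared pixels.
#' @export
convex_hull_area <- function(track) {
  tr <- get_xy(track)
  pts <- unique(cbind(tr$x, tr$y))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  if (length(h) < 3) return(0)
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Straightness index of a track segment
#'
#' Chord distance between the endpoints of the segment divided by the path
#' length along it; 1 for a perfectly straight monotone path, approaching 0
#' for a closed loop. Undefined (`NA`) when the path length is zero.
#'
#' @inheritParams path_length
#' @return Dimensionless value in `[0, 1]`, or `NA` if the segment has zero
#'   path length.
#' @export
straightness <- function(track, i = 1, j = NULL) {
  tr <- get_xy(track)
  if (is.null(j)) j <- nrow(tr)
  len <- path_length(tr, i, j)
  if (len == 0) return(NA_real_)
  chord <- sqrt((tr$x[j] - tr$x[i])^2 + (tr$y[j] - tr$y[i])^2)
  chord / len
}

#' Intensity of use of an area
#'
#' Trajectory length divided by the square root of the covered (convex hull)
#' area — a classic movement-ecology metric: high values mean dense re-use of
#' a small area. Scale-invariant: any square perimeter path scores 4.
#' Undefined (`NA`) when the area is zero (degenerate hull); 0 when the
#' length is zero over a positive area.
#'
#' @param total_length Trajectory length in pixels, `>= 0`.
#' @param area Covered area in squared pixels, `>= 0`.
#' @return Dimensionless ratio, or `NA` when `area == 0`.
#' @export
intensity_of_use <- function(total_length, area) {
  if (!is.numeric(total_length) || !is.numeric(area) ||
      total_length < 0 || area < 0) {
    stop("total_length and area must be non-negative numbers", call. = FALSE)
  }
  if (area == 0) return(NA_real_)
  total_length / sqrt(area)
}

#' Contact time and contact ratio of a trial
#'
#' @param trial A [tracked_trial()].
#' @return A list with `total_contact` — time in seconds spent in proximity
#'   to the stranger (in-contact frames / fps) — and `contact_ratio`, the
#'   fraction of track frames in contact.
#' @export
contact_stats <- function(trial) {
  stopifnot(inherits(trial, "tracked_trial"))
  tr <- trial$track
  if (nrow(tr) == 0) stop("contact_stats is undefined for an empty track",
                          call. = FALSE)
  n_in <- sum(in_contact(tr$x, tr$y, trial$arena))
  list(total_contact = n_in / trial$arena$fps,
       contact_ratio = n_in / nrow(tr))
}

#' Compute the full movement-feature panel for one trial
#'
#' Assembles the eleven features of [feature_names()] from a preprocessed
#' trial:
#' * `time_until_approach` — time from trial start to first proximity to the
#'   stranger (seconds);
#' * `duration_of_approach` — time from approach onset to first proximity;
#' * `speed_of_first_approach` — mean speed over the onset..contact path
#'   (px/s);
#' * `trajectory_length`, `trajectory_length_until_first_approach` (px);
#' * `area` — convex-hull area (px^2) and `intensity_of_use`;
#' * `total_contact` (s) and `contact_ratio`;
#' * `straightness` over the whole track and
#'   `straightness_until_first_approach` over start..approach.
#'
#' Trials in which the animal never comes into proximity have no approach
#' point; under the default `"censor"` policy `time_until_approach` is
#' imputed as the trial duration (the approach is right-censored at trial
#' end) and the other approach-dependent features are `NA`; under `"drop"`
#' all approach-dependent features are `NA`. Contact features are 0 either
#' way, and the `approached` flag records which case occurred.
#'
#' @param trial A preprocessed [tracked_trial()].
#' @param onset_band Passed to [detect_approach_events()].
#' @param never_approached Missing-value policy for never-approached trials,
#'   `"censor"` (default) or `"drop"`.
#' @return A one-row tibble: `trial_id`, the eleven features, `approached`.
#' @export
compute_features <- function(trial, onset_band = NULL,
                             never_approached = c("censor", "drop")) {
  stopifnot(inherits(trial, "tracked_trial"))
  never_approached <- match.arg(never_approached)
  tr <- trial$track
  if (nrow(tr) == 0) stop("features are undefined for an empty track",
                          call. = FALSE)
  ev <- detect_approach_events(trial, onset_band = onset_band)
  cs <- contact_stats(trial)
  total_len <- path_length(tr)
  hull <- convex_hull_area(tr)

  if (ev$approached) {
    time_until <- ev$t_A
    dur <- ev$t_A - ev$t_onset
    len_until <- path_length(tr, 1, ev$i_A)
    approach_len <- path_length(tr, ev$i_onset, ev$i_A)
    speed <- if (dur > 0) approach_len / dur else NA_real_
    str_until <- if (ev$i_A > 1) straightness(tr, 1, ev$i_A) else NA_real_
  } else {
    time_until <- switch(never_approached,
                         censor = trial$arena$trial_duration,
                         drop = NA_real_)
    dur <- speed <- len_until <- str_until <- NA_real_
  }

  tibble::tibble(
    trial_id = trial$trial_id,
    time_until_approach = time_until,
    duration_of_approach = dur,
    speed_of_first_approach = speed,
    trajectory_length = total_len,
    trajectory_length_until_first_approach = len_until,
    area = hull,
    intensity_of_use = intensity_of_use(total_len, hull),
    total_contact = cs$total_contact,
    straightness = straightness(tr),
    straightness_until_first_approach = str_until,
    contact_ratio = cs$contact_ratio,
    approached = ev$approached
  )
}

#' Build the trials-by-features table
#'
#' One row per trial, keyed by `trial_id`, with the eleven features in the
#' fixed order of [feature_names()] plus the `approached` flag. Missing
#' values are explicit `NA`s (see [compute_features()] for when they arise).
#'
#' @param trials A non-empty list of preprocessed [tracked_trial()] objects
#'   with distinct `trial_id`s.
#' @inheritParams compute_features
#' @return A tibble with `length(trials)` rows.
#' @export
build_feature_table <- function(trials, onset_band = NULL,
                                never_approached = c("censor", "drop")) {
  stopifnot(is.list(trials), length(trials) >= 1)
  never_approached <- match.arg(never_approached)
  ids <- purrr::map_chr(trials, "trial_id")
  if (anyDuplicated(ids)) {
    stop("duplicate trial_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  purrr::map(trials, compute_features, onset_band = onset_band,
             never_approached = never_approached) |>
    purrr::list_rbind()
}
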