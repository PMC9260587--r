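# Data model and JSON interchange for tracked behavioral-test trials.

#' Arena and stranger geometry for a behavioral-test trial
#'
#' Describes the physical setup of a standardized trial: a rectangular arena
#' viewed from a ceiling camera (image coordinates: origin top-left, x right,
#' y down, units pixels), a stationary "stranger" seated at a fixed marked
#' location modeled as a circle, and a contact band around that circle within
#' which the animal counts as being in proximity.
#'
#' @param width,height Arena size in pixels (the video frame size).
#' @param fps Frames per second of the tracking data.
#' @param stranger_center Numeric length-2, `(x, y)` pixel position of the
#'   stranger.
#' @param stranger_radius Radius in pixels of the circle occupied by the
#'   stranger.
#' @param contact_threshold Distance in pixels beyond the stranger circle that
#'   still counts as proximity ("contact"). A point is in contact when its
#'   distance to `stranger_center` is at most
#'   `stranger_radius + contact_threshold` (boundary inclusive).
#' @param trial_duration Nominal trial length in seconds.
#'
#' @return An object of class `arena_config`.
#' @examples
#' arena_config() # the default 1280 x 960 px, 30 FPS, 40 s setup
#' @export
arena_config <- function(width = 1280, height = 960, fps = 30,
                         stranger_center = c(width / 2, height / 2),
                         stranger_radius = 60,
                         contact_threshold = 120,
                         trial_duration = 40) {
  stopifnot(
    is.numeric(width), length(width) == 1, width > 0,
    is.numeric(height), length(height) == 1, height > 0,
    is.numeric(fps), length(fps) == 1, fps > 0,
    is.numeric(trial_duration), length(trial_duration) == 1, trial_duration > 0,
    is.numeric(stranger_center), length(stranger_center) == 2,
    is.numeric(stranger_radius), length(stranger_radius) == 1, stranger_radius > 0,
    is.numeric(contact_threshold), length(contact_threshold) == 1,
    contact_threshold >= 0
  )
  sx <- stranger_center[1]; sy <- stranger_center[2]
  if (sx - stranger_radius < 0 || sx + stranger_radius > width ||
      sy - stranger_radius < 0 || sy + stranger_radius > height) {
    stop("stranger circle must lie fully inside the arena", call. = FALSE)
  }
  structure(
    list(
      width = as.numeric(width), height = as.numeric(height),
      fps = as.numeric(fps),
      stranger_center = as.numeric(stranger_center),
      stranger_radius = as.numeric(stranger_radius),
      contact_threshold = as.numeric(contact_threshold),
      trial_duration = as.numeric(trial_duration)
    ),
    class = "arena_config"
  )
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf(
    "<arena_config> %g x %g px, %g FPS, %g s; stranger at (%g, %g) r=%g, contact band %g px\n",
    x$width, x$height, x$fps, x$trial_duration,
    x$stranger_center[1], x$stranger_center[2],
    x$stranger_radius, x$contact_threshold
  ))
  invisible(x)
}

#' Nominal number of frames in a trial
#'
#' @param arena An [arena_config()].
#' @return Integer, `round(fps * trial_duration)`.
#' @export
n_frames <- function(arena) {
  stopifnot(inherits(arena, "arena_config"))
  as.integer(round(arena$fps * arena$trial_duration))
}

#' Construct a tracked trial
#'
#' A tracked trial is one behavioral-test trial's position time series for a
#' single animal, together with the arena geometry. The track is a tibble with
#' one row per detected frame; frames at which the detector lost the animal
#' are simply absent (gaps), never encoded as zero coordinates.
#'
#' @param trial_id Character scalar identifying the trial.
#' @param track A data frame with columns `frame` (0-based integer, strictly
#'   increasing), `x`, `y` (pixels), and optionally `confidence` (detection
#'   certainty in `[0, 1]`, `NA` when unknown) and `interpolated` (logical,
#'   `TRUE` for gap-filled points). `t` (seconds) is derived as `frame / fps`.
#' @param arena An [arena_config()].
#' @param subject_meta Optional named list of subject-level metadata (e.g.,
#'   the key of a row in an external score table).
#'
#' @return An object of class `tracked_trial`: a list with elements
#'   `trial_id`, `arena`, `track` (tibble with columns `frame`, `t`, `x`, `y`,
#'   `confidence`, `interpolated`) and `subject_meta`.
#' @export
tracked_trial <- function(trial_id, track, arena, subject_meta = list()) {
  stopifnot(is.character(trial_id), length(trial_id) == 1,
            inherits(arena, "arena_config"), is.list(subject_meta))
  track <- tibble::as_tibble(track)
  required <- c("frame", "x", "y")
  missing_cols <- setdiff(required, names(track))
  if (length(missing_cols) > 0) {
    stop("track is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"confidence" %in% names(track)) track$confidence <- NA_real_
  if (!"interpolated" %in% names(track)) track$interpolated <- FALSE
  if (nrow(track) > 0) {
    if (any(track$frame < 0) || any(track$frame != round(track$frame))) {
      stop("frame indices must be non-negative integers", call. = FALSE)
    }
    if (is.unsorted(track$frame, strictly = TRUE)) {
      stop("frames must be strictly increasing within a track", call. = FALSE)
    }
    if (!all(is.finite(track$x)) || !all(is.finite(track$y))) {
      stop("track coordinates must be finite", call. = FALSE)
    }
    conf <- track$confidence
    if (any(!is.na(conf) & (conf < 0 | conf > 1))) {
      stop("confidence values must lie in [0, 1]", call. = FALSE)
    }
  }
  track$frame <- as.integer(track$frame)
  track$t <- track$frame / arena$fps
  track <- track[, c("frame", "t", "x", "y", "confidence", "interpolated")]
  structure(
    list(trial_id = trial_id, arena = arena, track = track,
         subject_meta = subject_meta),
    class = "tracked_trial"
  )
}

#' @export
print.tracked_trial <- function(x, ...) {
  cat(sprintf("<tracked_trial> '%s': %d detected frames / %d nominal (%.1f s at %g FPS)\n",
              x$trial_id, nrow(x$track), n_frames(x$arena),
              x$arena$trial_duration, x$arena$fps))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble tracked_trial
#' @export
as_tibble.tracked_trial <- function(x, ...) x$track

#' Read a tracked trial from its JSON interchange file
#'
#' The interchange schema is a single JSON object:
#' \preformatted{
#' {"trial_id": str, "fps": number, "frame_size": [w, h],
#'  "dog": [{"frame": int, "x": number, "y": number,
#'           "confidence": number|null}, ...],
#'  "stranger": {"x": number, "y": number, "radius": number}}
#' }
#' An absent or null `confidence` is read as `NA` (a detection whose certainty
#' is unknown). Frames must be strictly increasing.
#'
#' @param path Path to the JSON file.
#' @param arena Optional [arena_config()]. When `NULL`, the arena is built
#'   from the file's `fps`, `frame_size` and `stranger` fields, with the
#'   package defaults for `contact_threshold` and a `trial_duration` spanning
#'   the recorded frames. When supplied, it takes precedence (analysis
#'   parameters such as the contact band live in the config, not the file).
#'
#' @return A [tracked_trial()].
#' @seealso [write_trial_json()]
#' @export
read_trial_json <- function(path, arena = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("malformed JSON in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  for (field in c("trial_id", "fps", "frame_size", "dog")) {
    if (is.null(obj[[field]])) {
      stop("trial file '", path, "' is missing required field '", field, "'",
           call. = FALSE)
    }
  }
  dog <- obj$dog
  if (is.list(dog) && !is.data.frame(dog)) dog <- dplyr::bind_rows(dog)
  dog <- tibble::as_tibble(dog)
  for (field in c("frame", "x", "y")) {
    if (!field %in% names(dog)) {
      stop("trial file '", path, "': 'dog' records lack field '", field, "'",
           call. = FALSE)
    }
  }
  if (is.null(arena)) {
    st <- obj$stranger
    if (is.null(st)) {
      stop("trial file '", path,
           "' has no 'stranger' field and no arena was supplied", call. = FALSE)
    }
    dur <- if (nrow(dog) > 0) (max(dog$frame) + 1) / obj$fps else 1 / obj$fps
    arena <- arena_config(
      width = obj$frame_size[1], height = obj$frame_size[2], fps = obj$fps,
      stranger_center = c(st$x, st$y), stranger_radius = st$radius,
      trial_duration = dur
    )
  }
  tracked_trial(trial_id = obj$trial_id, track = dog, arena = arena)
}

#' Write a tracked trial to the JSON interchange format
#'
#' Numbers are written at full precision so that `read_trial_json()` of the
#' output reproduces the trial exactly. Missing confidences become `null`.
#' Note the interchange schema does not carry the `interpolated` flag; write
#' raw trials if the flag must survive a round trip.
#'
#' @param trial A [tracked_trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_json <- function(trial, path) {
  stopifnot(inherits(trial, "tracked_trial"))
  a <- trial$arena
  obj <- list(
    trial_id = trial$trial_id,
    fps = a$fps,
    frame_size = c(a$width, a$height),
    dog = trial$track[, c("frame", "x", "y", "confidence")],
    stranger = list(x = a$stranger_center[1], y = a$stranger_center[2],
                    radius = a$stranger_radius)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' Read every trial JSON file in a directory
#'
#' @param dir Directory containing `*.json` trial files.
#' @inheritParams read_trial_json
#' @return A list of [tracked_trial()] objects, in filename order.
#' @export
read_trial_dir <- function(dir, arena = NULL) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  if (length(files) == 0) stop("no trial JSON files in '", dir, "'", call. = FALSE)
  purrr::map(files, read_trial_json, arena = arena)
}
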