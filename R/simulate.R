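# Synthetic behavioral-test trials: a correlated biased random walk with
# contact dwell states, plus group-shifted synthetic external scores. The
# generator exists so the whole pipeline — features, scenario clustering,
# pattern explanation — can be validated end-to-end against known phenotype
# structure.

#' Generative parameters of a behavioral phenotype
#'
#' Parameters of the trial simulator's movement model, a correlated random
#' walk biased toward the stranger with a two-state (roam/dwell) contact
#' dynamic.
#'
#' @param approach_bias Weight in `[-1, 1]` pulling the heading toward the
#'   stranger at each step: 1 = heads straight at the stranger, 0 = pure
#'   correlated random walk, negative values = active aversion (the animal
#'   turns away from the stranger, as a fearful subject keeping distance).
#' @param mean_speed,speed_sd Per-frame speed draw, px/s (truncated at 0).
#' @param heading_noise_sd Gaussian heading noise per frame, radians.
#' @param dwell_prob Per-frame probability of settling into a contact dwell
#'   once within the contact zone.
#' @param leave_prob Per-frame probability of leaving a dwell.
#' @param start_region Where the trial starts: `"corner"` (far corner of the
#'   arena), `"edge"` (random point near the perimeter) or `"random"`
#'   (uniform outside the contact zone).
#' @return An object of class `phenotype_params`.
#' @export
phenotype_params <- function(approach_bias = 0.5, mean_speed = 150,
                             speed_sd = 30, heading_noise_sd = 0.4,
                             dwell_prob = 0.5, leave_prob = 0.1,
                             start_region = c("corner", "edge", "random")) {
  start_region <- match.arg(start_region)
  stopifnot(
    is.numeric(approach_bias), approach_bias >= -1, approach_bias <= 1,
    is.numeric(mean_speed), mean_speed >= 0,
    is.numeric(speed_sd), speed_sd >= 0,
    is.numeric(heading_noise_sd), heading_noise_sd >= 0,
    is.numeric(dwell_prob), dwell_prob >= 0, dwell_prob <= 1,
    is.numeric(leave_prob), leave_prob >= 0, leave_prob <= 1
  )
  structure(
    list(approach_bias = approach_bias, mean_speed = mean_speed,
         speed_sd = speed_sd, heading_noise_sd = heading_noise_sd,
         dwell_prob = dwell_prob, leave_prob = leave_prob,
         start_region = start_region),
    class = "phenotype_params"
  )
}

#' Reference phenotypes: approach-prone and avoidant
#'
#' Two fixed, well-separated phenotypes used throughout the package's
#' validation: an approach-prone animal that seeks out and dwells near the
#' stranger, and an avoidant one that wanders with little attraction and
#' leaves contact quickly. The two differ only in approach tendency and
#' contact dwell — locomotor parameters (speed, heading noise) are shared —
#' so the contrast the pipeline should discover lives in the social features
#' (contact time, approach timing), not in generic movement statistics. The
#' avoidant phenotype carries a negative approach bias: it does not merely
#' fail to seek the stranger, it actively keeps its distance.
#'
#' @return A [phenotype_params()] object.
#' @export
phenotype_approach_prone <- function() {
  phenotype_params(approach_bias = 0.85, mean_speed = 160, speed_sd = 40,
                   heading_noise_sd = 0.35, dwell_prob = 0.92,
                   leave_prob = 0.03, start_region = "corner")
}

#' @rdname phenotype_approach_prone
#' @export
phenotype_avoidant <- function() {
  phenotype_params(approach_bias = -0.3, mean_speed = 160, speed_sd = 40,
                   heading_noise_sd = 0.35, dwell_prob = 0.05,
                   leave_prob = 0.5, start_region = "corner")
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Simulate one tracked trial
#'
#' Runs the movement model for exactly `round(fps * trial_duration)` frames.
#' Each roaming step blends the previous heading with the direction to the
#' stranger (weight `approach_bias`), adds Gaussian heading noise, and
#' advances by a truncated-Gaussian speed; positions are reflected at the
#' arena walls. Inside the contact zone the animal may settle into a dwell —
#' small jitter clamped to the zone — which it leaves with probability
#' `leave_prob` per frame, heading away from the stranger. Per-frame
#' detection confidences are drawn from a clipped Gaussian, and frames may be
#' dropped (detection loss) with probability `dropout`. Reproducible from
#' `seed`.
#'
#' @param params A [phenotype_params()].
#' @param arena An [arena_config()].
#' @param seed Integer seed.
#' @param trial_id Identifier for the resulting trial.
#' @param confidence List with `mean`, `sd` (clipped-Gaussian confidence
#'   model) and `dropout` (per-frame probability of a missed detection).
#' @return A [tracked_trial()].
#' @export
simulate_trial <- function(params, arena = arena_config(), seed = 1,
                           trial_id = "sim",
                           confidence = list(mean = 0.9, sd = 0.05,
                                             dropout = 0)) {
  stopifnot(inherits(params, "phenotype_params"),
            inherits(arena, "arena_config"))
  n <- n_frames(arena)
  dt <- 1 / arena$fps
  sc <- arena$stranger_center
  contact_r <- arena$stranger_radius + arena$contact_threshold
  withr::with_seed(as.integer(seed), {
    start <- switch(params$start_region,
      corner = c(stats::runif(1, 0.03, 0.12) * arena$width,
                 stats::runif(1, 0.88, 0.97) * arena$height),
      edge = {
        side <- sample(4, 1)
        m <- 0.05
        switch(side,
          c(stats::runif(1, 0, arena$width), m * arena$height),
          c(stats::runif(1, 0, arena$width), (1 - m) * arena$height),
          c(m * arena$width, stats::runif(1, 0, arena$height)),
          c((1 - m) * arena$width, stats::runif(1, 0, arena$height)))
      },
      random = {
        repeat {
          p <- c(stats::runif(1, 0, arena$width),
                 stats::runif(1, 0, arena$height))
          if (sqrt(sum((p - sc)^2)) > contact_r) break
        }
        p
      })
    x <- numeric(n); y <- numeric(n)
    x[1] <- start[1]; y[1] <- start[2]
    heading <- stats::runif(1, -pi, pi)
    dwelling <- FALSE
    for (i in seq_len(n - 1)) {
      pos <- c(x[i], y[i])
      d_str <- sqrt(sum((pos - sc)^2))
      in_zone <- d_str <= contact_r
      if (dwelling) {
        if (stats::runif(1) < params$leave_prob) {
          dwelling <- FALSE
          heading <- atan2(pos[2] - sc[2], pos[1] - sc[1])  # head away
        }
      } else if (in_zone && stats::runif(1) < params$dwell_prob) {
        dwelling <- TRUE
      }
      if (dwelling) {
        cand <- pos + stats::rnorm(2, 0, 4)
        d_new <- sqrt(sum((cand - sc)^2))
        if (d_new > contact_r) {            # clamp back inside the zone
          cand <- sc + (cand - sc) * (contact_r / d_new) * 0.98
        }
        x[i + 1] <- cand[1]; y[i + 1] <- cand[2]
      } else {
        target <- atan2(sc[2] - pos[2], sc[1] - pos[1])
        heading <- heading +
          params$approach_bias * wrap_angle(target - heading) +
          stats::rnorm(1, 0, params$heading_noise_sd)
        speed <- max(0, stats::rnorm(1, params$mean_speed, params$speed_sd))
        cand <- pos + speed * dt * c(cos(heading), sin(heading))
        # reflect at walls
        if (cand[1] < 0) cand[1] <- -cand[1]
        if (cand[1] > arena$width) cand[1] <- 2 * arena$width - cand[1]
        if (cand[2] < 0) cand[2] <- -cand[2]
        if (cand[2] > arena$height) cand[2] <- 2 * arena$height - cand[2]
        cand[1] <- min(max(cand[1], 0), arena$width)
        cand[2] <- min(max(cand[2], 0), arena$height)
        if (any(cand != pos + speed * dt * c(cos(heading), sin(heading)))) {
          heading <- atan2(cand[2] - pos[2], cand[1] - pos[1])
        }
        x[i + 1] <- cand[1]; y[i + 1] <- cand[2]
      }
    }
    conf <- pmin(1, pmax(0, stats::rnorm(n, confidence$mean, confidence$sd)))
    keep <- rep(TRUE, n)
    if (confidence$dropout > 0) {
      keep <- stats::runif(n) >= confidence$dropout
      keep[1] <- TRUE                        # never lose the start point
    }
    track <- tibble::tibble(frame = (seq_len(n) - 1L)[keep],
                            x = x[keep], y = y[keep],
                            confidence = conf[keep])
  })
  tracked_trial(trial_id, track, arena)
}

#' Specify a simulated cohort
#'
#' @param groups A list of groups, each a list with elements `params` (a
#'   [phenotype_params()]), `n` (number of trials) and optionally `label`.
#' @param arena An [arena_config()]; the default mirrors the standard test
#'   setup (1280 x 960 px, 30 FPS, 40 s).
#' @param seed Integer master seed.
#' @param confidence Confidence model passed to [simulate_trial()].
#' @param score_model Synthetic external-score model: list with `columns`
#'   (score names), `base` (grand mean), `effect` (additive shift per group
#'   index), `noise_sd`, and `sign` (per-column sign of the group effect,
#'   recycled). `effect = 0` makes scores independent of group (a null
#'   cohort).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, arena = arena_config(), seed = 1,
                        confidence = list(mean = 0.9, sd = 0.05, dropout = 0),
                        score_model = list(columns = c("SDF", "SDA", "PS"),
                                           base = 2, effect = 1.5,
                                           noise_sd = 0.8, sign = 1)) {
  stopifnot(is.list(groups), length(groups) >= 1,
            inherits(arena, "arena_config"))
  total <- sum(vapply(groups, function(g) g$n, numeric(1)))
  if (total < 4) stop("cohort must have at least 4 trials", call. = FALSE)
  for (g in groups) {
    if (!inherits(g$params, "phenotype_params")) {
      stop("each group needs a phenotype_params object", call. = FALSE)
    }
  }
  structure(
    list(groups = groups, arena = arena, seed = as.integer(seed),
         confidence = confidence, score_model = score_model),
    class = "cohort_spec"
  )
}

trial_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483647L)
}

#' Simulate synthetic external scores for grouped subjects
#'
#' Each score column is `base + effect * sign * (group index - 1) + noise`,
#' so with `effect = 0` scores carry no group signal.
#'
#' @param labels Tibble with columns `trial_id` and `group` (1-based index).
#' @param score_model See [cohort_spec()].
#' @param seed Integer seed.
#' @return Tibble: `trial_id` plus one numeric column per score.
#' @export
simulate_scores <- function(labels, score_model, seed = 1) {
  stopifnot(is.data.frame(labels), all(c("trial_id", "group") %in% names(labels)))
  cols <- score_model$columns
  sign <- rep_len(score_model$sign %||% 1, length(cols))
  withr::with_seed(as.integer(seed), {
    out <- tibble::tibble(trial_id = labels$trial_id)
    for (j in seq_along(cols)) {
      out[[cols[j]]] <- score_model$base +
        score_model$effect * sign[j] * (labels$group - 1) +
        stats::rnorm(nrow(labels), 0, score_model$noise_sd)
    }
    out
  })
}

#' Simulate a cohort of trials with known phenotype structure
#'
#' @param spec A [cohort_spec()].
#' @return A list with `trials` (list of [tracked_trial()]), `labels`
#'   (tibble: `trial_id`, `group` (1-based index), `label`) — ground truth
#'   for recovery tests only, never written into trial files — and `scores`
#'   (synthetic score tibble from [simulate_scores()]).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grp_idx <- integer(0); grp_lab <- character(0)
  params_list <- list()
  for (g in seq_along(spec$groups)) {
    grp <- spec$groups[[g]]
    grp_idx <- c(grp_idx, rep(g, grp$n))
    grp_lab <- c(grp_lab, rep(grp$label %||% sprintf("group%d", g), grp$n))
    params_list <- c(params_list, rep(list(grp$params), grp$n))
  }
  n_total <- length(grp_idx)
  ids <- sprintf("trial_%03d", seq_len(n_total))
  trials <- purrr::map(seq_len(n_total), function(i) {
    simulate_trial(params_list[[i]], arena = spec$arena,
                   seed = trial_seed(spec$seed, i), trial_id = ids[i],
                   confidence = spec$confidence)
  })
  labels <- tibble::tibble(trial_id = ids, group = grp_idx, label = grp_lab)
  scores <- simulate_scores(labels, spec$score_model,
                            seed = trial_seed(spec$seed, n_total + 1))
  list(trials = trials, labels = labels, scores = scores)
}
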