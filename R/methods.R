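# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a scenario table
#'
#' @param x A `scenario_table` from [enumerate_scenarios()].
#' @param ... Unused.
#' @return A plain tibble, one row per scenario.
#' @method tidy scenario_table
#' @export
tidy.scenario_table <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidy.scenario_table
#' @method glance scenario_table
#' @export
glance.scenario_table <- function(x, ...) {
  tibble::tibble(
    n_scenarios = nrow(x),
    best_silhouette = if (nrow(x) > 0) max(x$silhouette) else NA_real_,
    best_n_pcs = if (nrow(x) > 0) x$n_pcs[1] else NA_integer_,
    best_k = if (nrow(x) > 0) x$k[1] else NA_integer_
  )
}

#' Tidy a pattern report
#'
#' @param x A `pattern_report` from [explanatory_features()].
#' @param ... Unused.
#' @return Tibble of explanatory features: `cluster`, `feature`, `direction`,
#'   `H`, `L`, `support`.
#' @method tidy pattern_report
#' @export
tidy.pattern_report <- function(x, ...) x$patterns

#' @rdname tidy.pattern_report
#' @method glance pattern_report
#' @export
glance.pattern_report <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_candidates = length(x$candidates),
    n_explanatory = length(unique(x$patterns$feature))
  )
}

#' Tidy a score comparison
#'
#' @param x A `score_comparison` from [compare_external_scores()].
#' @param ... Unused.
#' @return The per-score rank-sum test tibble.
#' @method tidy score_comparison
#' @export
tidy.score_comparison <- function(x, ...) x$tests

#' @rdname tidy.score_comparison
#' @method glance score_comparison
#' @export
glance.score_comparison <- function(x, ...) {
  tibble::tibble(
    n_scores = length(unique(x$descriptives$score)),
    n_tests = nrow(x$tests),
    min_p_value = if (nrow(x$tests) > 0) min(x$tests$p_value) else NA_real_
  )
}

#' Tidy a full pipeline result
#'
#' @param x A `pattern_discovery` from [run_pipeline()].
#' @param ... Unused.
#' @return The scenario tibble of the run.
#' @method tidy pattern_discovery
#' @export
tidy.pattern_discovery <- function(x, ...) tidy(x$scenarios)

#' @rdname tidy.pattern_discovery
#' @method glance pattern_discovery
#' @export
glance.pattern_discovery <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_trials = nrow(x$qc), n_retained = sum(x$qc$retained)),
    glance(x$scenarios)
  )
}

#' Plot a tracked trial
#'
#' Trajectory over the arena with the stranger circle and contact zone; the
#' start point is marked.
#'
#' @param object A [tracked_trial()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tracked_trial
#' @export
autoplot.tracked_trial <- function(object, ...) {
  a <- object$arena
  circle <- function(r) {
    th <- seq(0, 2 * pi, length.out = 181)
    tibble::tibble(x = a$stranger_center[1] + r * cos(th),
                   y = a$stranger_center[2] + r * sin(th))
  }
  ggplot2::ggplot(object$track, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(ggplot2::aes(color = .data$t), linewidth = 0.4) +
    ggplot2::geom_path(data = circle(a$stranger_radius), linetype = 1) +
    ggplot2::geom_path(data = circle(a$stranger_radius + a$contact_threshold),
                       linetype = 2) +
    ggplot2::geom_point(data = object$track[1, ], shape = 17, size = 2) +
    ggplot2::scale_y_reverse() +               # image coordinates: y down
    ggplot2::coord_fixed(xlim = c(0, a$width), ylim = c(a$height, 0)) +
    ggplot2::labs(title = object$trial_id, x = "x (px)", y = "y (px)",
                  color = "t (s)")
}

#' Plot a scenario table
#'
#' Silhouette score against the number of principal components, annotated
#' with the elbow-chosen k and retained-cluster count.
#'
#' @param object A `scenario_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scenario_table
#' @export
autoplot.scenario_table <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_pcs, y = .data$silhouette)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("k=%d (%d kept)", .data$k,
                                   .data$n_retained_clusters)),
      vjust = -0.8, size = 3) +
    ggplot2::labs(x = "principal components", y = "silhouette score")
}

#' Plot a pattern report
#'
#' Boxplots of each explanatory feature by retained cluster, the visual
#' counterpart of the High/Low pattern lines.
#'
#' @param object A `pattern_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pattern_report
#' @export
autoplot.pattern_report <- function(object, ...) {
  feats <- unique(object$patterns$feature)
  if (length(feats) == 0) feats <- object$candidates
  d <- tidyr::pivot_longer(object$data, dplyr::all_of(feats),
                           names_to = "feature", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$cluster),
                                  y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "cluster", y = "feature value")
}

#' Plot a score comparison
#'
#' Boxplots of each external score by retained cluster.
#'
#' @param object A `score_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot score_comparison
#' @export
autoplot.score_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = factor(.data$cluster),
                                            y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~score, scales = "free_y") +
    ggplot2::labs(x = "cluster", y = "score")
}
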