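# Cluster characterization: PCA-loading importance screening, directional
# H/L counts, explanatory features, and comparison against external scores.
#
# The directional statistic: for a feature f and a cluster C within a cluster
# set, H(f) counts members of C with value >= the grand mean of f over all
# retained samples, L(f) counts members strictly below it (so H + L = |C|).
# f "up-explains" C when H > L, "down-explains" it when L > H. f is
# up-explanatory for C when it up-explains C and down-explains every other
# cluster (dually for down-explanatory): the majority of C sits on one side
# of the grand mean and the majority of every other cluster on the other.

#' Assemble a cluster set for pattern explanation
#'
#' Gathers retained samples, their feature values and cluster assignments,
#' and the grand mean of every feature pooled over all retained samples (the
#' reference point of the directional statistic). Samples labeled `NA`
#' (outliers) are excluded throughout, including from the grand means. Any
#' remaining missing feature values are imputed with the retained-sample
#' column mean.
#'
#' @param features A feature table (data frame with `trial_id` and numeric
#'   feature columns) or a numeric matrix with sample rownames.
#' @param labels Named integer vector of cluster ids (`NA` = outlier); names
#'   must match the feature rows.
#' @return An object of class `cluster_set`: list with `data` (tibble:
#'   `trial_id`, `cluster`, one column per feature), `grand_means` (named
#'   numeric), `features` (feature names) and `sizes` (tibble `cluster`,
#'   `size`).
#' @export
cluster_set <- function(features, labels) {
  if (is.data.frame(features)) {
    ids <- as.character(features$trial_id)
    num <- names(features)[vapply(features, is.numeric, logical(1))]
    num <- setdiff(num, "trial_id")
    mat <- as.matrix(features[, num, drop = FALSE])
    rownames(mat) <- ids
  } else {
    mat <- as.matrix(features)
    if (is.null(rownames(mat))) stop("feature matrix needs rownames",
                                     call. = FALSE)
  }
  if (is.null(names(labels))) {
    stopifnot(length(labels) == nrow(mat))
    names(labels) <- rownames(mat)
  }
  common <- intersect(rownames(mat), names(labels))
  if (length(common) == 0) stop("no samples shared between features and labels",
                                call. = FALSE)
  labels <- labels[common]
  mat <- mat[common, , drop = FALSE]
  keep <- !is.na(labels)
  mat <- mat[keep, , drop = FALSE]
  labels <- labels[keep]
  if (nrow(mat) == 0) stop("no retained samples", call. = FALSE)
  for (j in seq_len(ncol(mat))) {
    nas <- is.na(mat[, j])
    if (any(nas)) mat[nas, j] <- mean(mat[!nas, j])
  }
  sizes <- table(labels)
  structure(
    list(
      data = dplyr::bind_cols(
        tibble::tibble(trial_id = rownames(mat),
                       cluster = as.integer(labels)),
        tibble::as_tibble(mat)),
      grand_means = colMeans(mat),
      features = colnames(mat),
      sizes = tibble::tibble(cluster = as.integer(names(sizes)),
                             size = as.integer(sizes))
    ),
    class = "cluster_set"
  )
}

#' PCA-loading importance of each feature
#'
#' The importance of feature `f` on component `j` is the absolute value of
#' its loading, restricted to the first `n_pcs` components actually used by a
#' scenario.
#'
#' @param pca A `pca_projection` from [fit_pca()].
#' @param n_pcs Number of leading components to keep (default: all).
#' @return A features-by-components matrix of non-negative importances.
#' @export
pca_feature_importance <- function(pca, n_pcs = NULL) {
  stopifnot(inherits(pca, "pca_projection"))
  if (is.null(n_pcs)) n_pcs <- pca$n_components
  stopifnot(n_pcs >= 1, n_pcs <= pca$n_components)
  abs(pca$loadings[, seq_len(n_pcs), drop = FALSE])
}

#' Screen candidate explanatory features by median importance
#'
#' A feature is a candidate when its importance strictly exceeds the median
#' importance (taken across features) on at least one principal component of
#' the scenario's model. With the strict inequality, a component on which all
#' features load equally nominates no candidates.
#'
#' @param importance A features-by-components importance matrix
#'   ([pca_feature_importance()]), or with `per_component = FALSE` the median
#'   is taken globally over the whole matrix.
#' @param per_component Take the median per component (default) or globally.
#' @return Character vector of candidate feature names, in the input's row
#'   order.
#' @export
candidate_features <- function(importance, per_component = TRUE) {
  stopifnot(is.matrix(importance), ncol(importance) >= 1)
  if (per_component) {
    med <- apply(importance, 2, stats::median)
    hit <- sweep(importance, 2, med, `>`)
  } else {
    hit <- importance > stats::median(importance)
  }
  rownames(importance)[apply(hit, 1, any)]
}

#' Directional H/L counts of a feature within a cluster
#'
#' Counts cluster members at or above (`H`) and strictly below (`L`) the
#' grand mean of the feature over all retained samples; ties at the mean
#' count toward `H`. Direction is `"up"` when `H > L`, `"down"` when
#' `L > H`, `"none"` on a tie; support is `H` for up, `L` for down.
#'
#' @param cs A [cluster_set()].
#' @param feature Feature name.
#' @param cluster Cluster id.
#' @return One-row tibble: `feature`, `cluster`, `H`, `L`, `direction`,
#'   `support`.
#' @export
direction_counts <- function(cs, feature, cluster) {
  stopifnot(inherits(cs, "cluster_set"))
  if (!feature %in% cs$features) stop("unknown feature '", feature, "'",
                                      call. = FALSE)
  if (!cluster %in% cs$sizes$cluster) stop("unknown cluster ", cluster,
                                           call. = FALSE)
  vals <- cs$data[[feature]][cs$data$cluster == cluster]
  m <- cs$grand_means[[feature]]
  H <- sum(vals >= m)
  L <- sum(vals < m)
  direction <- if (H > L) "up" else if (L > H) "down" else "none"
  support <- switch(direction, up = H, down = L, none = NA_integer_)
  tibble::tibble(feature = feature, cluster = as.integer(cluster),
                 H = as.integer(H), L = as.integer(L),
                 direction = direction, support = as.integer(support))
}

#' Find the explanatory features of every cluster
#'
#' Evaluates the directional statistic for every candidate feature and
#' cluster and keeps the explanatory ones: a feature is up-explanatory for a
#' cluster when it up-explains it and down-explains every other cluster in
#' the set (dually for down-explanatory). In a two-cluster set a feature
#' explanatory for one cluster is therefore explanatory, with opposite
#' direction, for the other.
#'
#' @param cs A [cluster_set()] with at least two clusters.
#' @param candidates Candidate feature names (e.g., from
#'   [candidate_features()]); default: all features of the set.
#' @param importance Optional importance matrix, carried into the report for
#'   provenance.
#' @param scenario Optional scenario number, carried into the report.
#' @return An object of class `pattern_report`: list with `patterns` (tibble
#'   of explanatory features: `cluster`, `feature`, `direction`, `H`, `L`,
#'   `support`), `directions` (the full candidate-by-cluster direction
#'   table), `candidates`, `clusters` (tibble `cluster`, `size`), `data`
#'   (the cluster-set data, for plotting) and `scenario`.
#' @export
explanatory_features <- function(cs, candidates = NULL, importance = NULL,
                                 scenario = NA_integer_) {
  stopifnot(inherits(cs, "cluster_set"))
  if (nrow(cs$sizes) < 2) {
    stop("explanatory features need at least 2 clusters", call. = FALSE)
  }
  if (is.null(candidates)) candidates <- cs$features
  candidates <- intersect(cs$features, candidates)  # keep canonical order
  clusters <- cs$sizes$cluster
  dirs <- purrr::map(candidates, function(f) {
    purrr::map(clusters, function(cl) direction_counts(cs, f, cl)) |>
      purrr::list_rbind()
  }) |> purrr::list_rbind()
  patterns <- purrr::map(candidates, function(f) {
    d <- dirs[dirs$feature == f, ]
    purrr::map(clusters, function(cl) {
      own <- d$direction[d$cluster == cl]
      rest <- d$direction[d$cluster != cl]
      expl <- (own == "up" && all(rest == "down")) ||
              (own == "down" && all(rest == "up"))
      if (expl) d[d$cluster == cl, ] else NULL
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (is.null(patterns) || nrow(patterns) == 0) {
    patterns <- dirs[0, ]
  }
  patterns <- dplyr::arrange(patterns, .data$cluster,
                             match(.data$feature, cs$features))
  patterns <- patterns[, c("cluster", "feature", "direction", "H", "L",
                           "support")]
  structure(
    list(patterns = patterns, directions = dirs, candidates = candidates,
         clusters = cs$sizes, data = cs$data, importance = importance,
         scenario = scenario),
    class = "pattern_report"
  )
}

#' Render a pattern report as text
#'
#' One line per cluster, `"Cluster <id> - High <feature>, Low <feature>,
#' ..."` in the canonical feature order (underscores shown as spaces);
#' clusters without explanatory features render as
#' `"Cluster <id> - no explanatory features"`. Pure function of the report.
#'
#' @param report A `pattern_report` from [explanatory_features()].
#' @return Character vector, one line per cluster.
#' @export
render_patterns <- function(report) {
  stopifnot(inherits(report, "pattern_report"))
  vapply(report$clusters$cluster, function(cl) {
    rows <- report$patterns[report$patterns$cluster == cl, ]
    if (nrow(rows) == 0) {
      sprintf("Cluster %d - no explanatory features", cl)
    } else {
      parts <- sprintf("%s %s",
                       ifelse(rows$direction == "up", "High", "Low"),
                       gsub("_", " ", rows$feature))
      sprintf("Cluster %d - %s", cl, paste(parts, collapse = ", "))
    }
  }, character(1))
}

#' @export
print.pattern_report <- function(x, ...) {
  cat("<pattern_report>",
      if (!is.na(x$scenario)) sprintf(" scenario %d", x$scenario) else "",
      "\n", sep = "")
  cat(paste0("  ", render_patterns(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Compare retained clusters on external per-subject scores
#'
#' Joins an external score table (e.g., questionnaire factor scores) to the
#' retained cluster labels and, per score column, reports per-cluster
#' descriptive statistics and — when exactly two clusters are retained — a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test. The test is exact for
#' small untied samples and otherwise uses the normal approximation with tie
#' correction ([stats::wilcox.test()]'s convention). Subjects missing a score
#' are excluded from that column's comparison, with the count logged; with
#' more than two clusters only descriptives are produced, with a warning.
#'
#' @param labels Named integer cluster labels (`NA` = outlier), e.g.
#'   `select_scenario(...)$labels`.
#' @param scores Data frame with a `trial_id` column and numeric score
#'   columns.
#' @return An object of class `score_comparison`: list with `descriptives`
#'   (tibble: `score`, `cluster`, `n`, `mean`, `median`, `q25`, `q75`),
#'   `tests` (tibble: `score`, `statistic`, `p_value`, `method`; empty when
#'   skipped), `n_missing` (tibble: `score`, `n_missing`) and `data` (the
#'   joined long table, for plotting).
#' @export
compare_external_scores <- function(labels, scores) {
  stopifnot(is.data.frame(scores), "trial_id" %in% names(scores))
  keep <- !is.na(labels)
  lab_tbl <- tibble::tibble(trial_id = names(labels)[keep],
                            cluster = as.integer(labels[keep]))
  score_cols <- setdiff(
    names(scores)[vapply(scores, is.numeric, logical(1))], "trial_id")
  if (length(score_cols) == 0) stop("no numeric score columns", call. = FALSE)
  joined <- dplyr::inner_join(lab_tbl,
                              dplyr::mutate(scores,
                                            trial_id = as.character(.data$trial_id)),
                              by = "trial_id")
  long <- tidyr::pivot_longer(joined, dplyr::all_of(score_cols),
                              names_to = "score", values_to = "value")
  n_missing <- long |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(n_missing = sum(is.na(.data$value)), .groups = "drop")
  if (any(n_missing$n_missing > 0)) {
    message("excluding missing scores: ",
            paste(sprintf("%s (%d)",
                          n_missing$score[n_missing$n_missing > 0],
                          n_missing$n_missing[n_missing$n_missing > 0]),
                  collapse = ", "))
  }
  long <- dplyr::filter(long, !is.na(.data$value))
  descriptives <- long |>
    dplyr::group_by(.data$score, .data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      median = stats::median(.data$value),
      q25 = unname(stats::quantile(.data$value, 0.25)),
      q75 = unname(stats::quantile(.data$value, 0.75)),
      .groups = "drop")
  clusters <- sort(unique(lab_tbl$cluster))
  if (length(clusters) != 2) {
    warning("rank-sum test needs exactly 2 retained clusters (got ",
            length(clusters), "); reporting descriptives only", call. = FALSE)
    tests <- tibble::tibble(score = character(), statistic = double(),
                            p_value = double(), method = character())
  } else {
    tests <- purrr::map(score_cols, function(sc) {
      d <- long[long$score == sc, ]
      g1 <- d$value[d$cluster == clusters[1]]
      g2 <- d$value[d$cluster == clusters[2]]
      if (length(g1) == 0 || length(g2) == 0) return(NULL)
      wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = NULL))
      tibble::tibble(score = sc, statistic = unname(wt$statistic),
                     p_value = wt$p.value, method = wt$method)
    }) |> purrr::list_rbind()
  }
  structure(
    list(descriptives = descriptives, tests = tests, n_missing = n_missing,
         data = long),
    class = "score_comparison"
  )
}

#' @export
print.score_comparison <- function(x, ...) {
  cat("<score_comparison>\n")
  print(x$descriptives)
  if (nrow(x$tests) > 0) {
    cat("Mann-Whitney U (two-sided):\n")
    print(x$tests)
  }
  invisible(x)
}
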