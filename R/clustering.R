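# Scenario clustering: standardization, PCA enumeration, elbow-selected
# k-means, silhouette scoring, outlier-cluster filtering.

#' Z-score a feature table
#'
#' Centers and scales every feature column to mean 0 and (population) sd 1,
#' the StandardScaler convention: sd uses the 1/n denominator. Missing values
#' are handled first, per `policy`: `"mean_impute"` (default) replaces each
#' `NA` by its column mean — after scaling such entries sit exactly at 0 —
#' while `"drop_rows"` removes rows with any missing feature. Constant
#' columns carry no information for clustering and are dropped with a
#' warning.
#'
#' @param table A feature table from [build_feature_table()], or any data
#'   frame with a `trial_id` column and numeric feature columns.
#' @param policy Missing-value policy, `"mean_impute"` or `"drop_rows"`.
#' @return An object of class `standardized_features`: list with `x` (the
#'   standardized matrix, rownames = trial ids), `center` and `scale` (named
#'   per-feature mean and population sd), `imputed` (the unscaled matrix
#'   after imputation), and `dropped` (names of dropped constant features).
#' @export
standardize_features <- function(table, policy = c("mean_impute", "drop_rows")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(table), nrow(table) >= 2)
  ids <- if ("trial_id" %in% names(table)) as.character(table$trial_id)
         else sprintf("row%d", seq_len(nrow(table)))
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "trial_id")
  if (length(num_cols) == 0) stop("no numeric feature columns", call. = FALSE)
  x <- as.matrix(table[, num_cols, drop = FALSE])
  rownames(x) <- ids
  if (policy == "drop_rows") {
    keep <- stats::complete.cases(x)
    x <- x[keep, , drop = FALSE]
    if (nrow(x) < 2) stop("fewer than 2 complete rows after dropping", call. = FALSE)
  } else {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- mean(x[!nas, j])
    }
  }
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  constant <- sd_pop == 0 | !is.finite(sd_pop)
  if (all(constant)) stop("all feature columns are constant", call. = FALSE)
  dropped <- colnames(x)[constant]
  if (length(dropped) > 0) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  keep_cols <- !constant
  z <- sweep(sweep(x[, keep_cols, drop = FALSE], 2, mu[keep_cols]),
             2, sd_pop[keep_cols], `/`)
  structure(
    list(x = z, center = mu[keep_cols], scale = sd_pop[keep_cols],
         imputed = x, dropped = dropped),
    class = "standardized_features"
  )
}

#' Principal component analysis of a standardized matrix
#'
#' Full PCA (all components up to numerical rank) of an already-standardized
#' matrix. Component signs are made deterministic: each loading vector is
#' flipped so its largest-magnitude entry is positive.
#'
#' @param x A `standardized_features` object or a numeric matrix whose
#'   columns are already centered.
#' @return An object of class `pca_projection`: list with `loadings`
#'   (features x components), `explained_variance_ratio`, `scores` (samples x
#'   components) and `n_components` (the numerical rank).
#' @export
fit_pca <- function(x) {
  if (inherits(x, "standardized_features")) x <- x$x
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) < 2 || ncol(x) < 1) stop("need at least 2 rows and 1 column",
                                       call. = FALSE)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  tol <- max(pc$sdev) * 1e-8
  rank <- sum(pc$sdev > tol)
  if (rank == 0) stop("input matrix has rank 0", call. = FALSE)
  rot <- pc$rotation[, seq_len(rank), drop = FALSE]
  sco <- pc$x[, seq_len(rank), drop = FALSE]
  for (j in seq_len(rank)) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(loadings = rot, explained_variance_ratio = evr[seq_len(rank)],
         scores = sco, n_components = rank),
    class = "pca_projection"
  )
}

kmeans_fit <- function(points, k, seed, nstart) {
  withr::with_seed(seed, {
    suppressWarnings(
      stats::kmeans(points, centers = k, nstart = nstart, iter.max = 100)
    )
  })
}

total_ss <- function(points) {
  sum(sweep(points, 2, colMeans(points))^2)
}

#' Choose k by the elbow method
#'
#' Fits k-means for each candidate `k` and locates the elbow of the
#' inertia-vs-k curve as the `k` maximizing the discrete curvature (second
#' difference) `I(k-1) - 2 I(k) + I(k+1)`, with `I(1)` taken as the total sum
#' of squares. No elbow is reported (`NA`) when the maximum curvature is not
#' unique, falls at the top of the scanned range (the true elbow may lie
#' beyond it), the points are degenerate (all identical), or the bend is not
#' prominent: a genuine elbow must bend by at least `prominence` of the
#' inertia remaining just before it (`curvature > prominence * I(k - 1)`).
#' The smooth, convex inertia decay of structureless data fails that bar, so
#' such data typically yields no elbow rather than a spurious small `k`.
#'
#' @param points Numeric matrix of sample coordinates (e.g., PCA scores).
#' @param k_min,k_max Candidate range; `k_max` is capped at `n - 1`.
#' @param seed Integer seed making the restarts reproducible.
#' @param nstart Random restarts per k-means fit.
#' @param prominence Minimum curvature, as a fraction of `I(k - 1)`, for a
#'   bend to count as an elbow.
#' @return The chosen `k`, or `NA_integer_` when no elbow is found.
#' @export
elbow_k <- function(points, k_min = 2, k_max = 10, seed = 1, nstart = 50,
                    prominence = 0.4) {
  points <- as.matrix(points)
  n <- nrow(points)
  k_max <- min(k_max, n - 1)
  stopifnot(k_min >= 2, k_min <= k_max)
  tss <- total_ss(points)
  if (tss < 1e-12) return(NA_integer_)  # all points identical
  ks <- (k_min - 1):min(k_max + 1, n)
  inertia <- vapply(ks, function(k) {
    if (k == 1) tss
    else kmeans_fit(points, k, seed = seed + k, nstart = nstart)$tot.withinss
  }, numeric(1))
  names(inertia) <- ks
  cand <- k_min:k_max
  cand <- cand[(cand - 1) >= min(ks) & (cand + 1) <= max(ks)]
  if (length(cand) == 0) return(NA_integer_)
  curv <- vapply(cand, function(k) {
    inertia[as.character(k - 1)] - 2 * inertia[as.character(k)] +
      inertia[as.character(k + 1)]
  }, numeric(1))
  best <- which(curv == max(curv))
  if (length(best) != 1) return(NA_integer_)       # tie: no unique elbow
  k_star <- cand[best]
  if (curv[best] <= prominence * inertia[as.character(k_star - 1)]) {
    return(NA_integer_)                            # bend not prominent
  }
  if (k_star == k_max) return(NA_integer_)         # elbow at scan boundary
  as.integer(k_star)
}

#' Fit k-means with canonical labels
#'
#' Euclidean k-means with `nstart` seeded random restarts. Cluster ids are
#' canonicalized by size: cluster 0 is the largest (ties broken by the
#' original label), so labels are stable descriptions, not initialization
#' artifacts. Deterministic given `seed`.
#'
#' @inheritParams elbow_k
#' @param k Number of clusters, `2 <= k <= n`.
#' @return A list with `labels` (integer vector of 0-based cluster ids, named
#'   by rownames of `points` when present), `inertia` (total within-cluster
#'   sum of squares), and `centers` (k x d matrix, rows in canonical order).
#' @export
cluster_kmeans <- function(points, k, seed = 1, nstart = 50) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")",
                  call. = FALSE)
  stopifnot(k >= 1)
  if (k == n) {
    # one point per cluster; Hartigan-Wong refuses this degenerate case
    labels <- seq_len(n) - 1L
    names(labels) <- rownames(points)
    return(list(labels = labels, inertia = 0, centers = points))
  }
  fit <- kmeans_fit(points, k, seed = seed, nstart = nstart)
  sizes <- tabulate(fit$cluster, nbins = k)
  ord <- order(-sizes, seq_len(k))          # decreasing size, stable ties
  relabel <- integer(k)
  relabel[ord] <- seq_len(k) - 1L
  labels <- relabel[fit$cluster]
  names(labels) <- rownames(points)
  list(labels = labels, inertia = fit$tot.withinss,
       centers = fit$centers[ord, , drop = FALSE])
}

#' Mean silhouette score of a labeling
#'
#' Mean per-sample silhouette width under euclidean distance, computed on all
#' samples before any outlier-cluster filtering. Samples in singleton
#' clusters get width 0 and are included in the mean (the convention of
#' [cluster::silhouette()], which performs the computation).
#'
#' @param points Numeric matrix of sample coordinates.
#' @param labels Integer cluster ids (any coding), length `nrow(points)`.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_avg <- function(points, labels) {
  points <- as.matrix(points)
  stopifnot(length(labels) == nrow(points))
  if (length(unique(labels)) < 2) {
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(points))
  mean(sil[, "sil_width"])
}

#' Discard clusters smaller than a minimum size
#'
#' Samples in clusters of fewer than `min_size` members are marked outliers
#' (`NA` label); retained clusters keep their original ids.
#'
#' @param labels Integer cluster ids, optionally named by sample id.
#' @param min_size Minimum retained cluster size, `>= 1`.
#' @return A list with `labels` (as input but `NA` for outliers), `outliers`
#'   (indices — or names, when available — of outlier samples), and
#'   `retained` (tibble with columns `cluster`, `size`, sorted by id).
#' @export
filter_outlier_clusters <- function(labels, min_size = 5) {
  stopifnot(is.numeric(min_size), min_size >= 1)
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_size]
  out <- labels
  is_out <- as.character(labels) %in% small
  out[is_out] <- NA
  retained_tbl <- tibble::tibble(
    cluster = as.integer(names(sizes)[!(names(sizes) %in% small)]),
    size = as.integer(sizes[!(names(sizes) %in% small)])
  ) |> dplyr::arrange(.data$cluster)
  outliers <- if (!is.null(names(labels))) names(labels)[is_out] else which(is_out)
  list(labels = out, outliers = outliers, retained = retained_tbl)
}

#' Enumerate all PCA/k-means clustering scenarios
#'
#' The scenario generator: for every possible dimensionality reduction —
#' keeping the first `n_pcs = 1, 2, ..., rank` principal components of the
#' standardized feature matrix — choose `k` by [elbow_k()], fit
#' [cluster_kmeans()], score the fit with [silhouette_avg()], and discard
#' clusters smaller than `min_cluster_size` as outliers. Scenarios for which
#' no elbow `k` is found are omitted. The result is sorted by silhouette,
#' best first, and is fully reproducible from `seed`.
#'
#' @param table A feature table ([build_feature_table()]) or any data frame
#'   with `trial_id` plus numeric feature columns; at least 4 rows.
#' @param k_range Length-2 integer vector, candidate k range for the elbow.
#' @param min_cluster_size Clusters smaller than this are discarded as
#'   outliers.
#' @param seed Integer seed governing all k-means restarts.
#' @param nstart Random restarts per k-means fit.
#' @param policy Missing-value policy for [standardize_features()].
#' @return A `scenario_table`: a tibble with one row per scenario — columns
#'   `scenario`, `n_pcs`, `silhouette`, `k`, `n_retained_clusters`,
#'   `n_retained_samples`, `retained_sizes` (a display string like
#'   `"14(c-0), 7(c-1)"`) — sorted by silhouette descending, carrying the
#'   per-scenario labels, the PCA fit and the standardization as attributes
#'   (see [scenario_labels()], [select_scenario()]).
#' @export
enumerate_scenarios <- function(table, k_range = c(2, 10), min_cluster_size = 5,
                                seed = 1, nstart = 50,
                                policy = c("mean_impute", "drop_rows")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(table), nrow(table) >= 4,
            length(k_range) == 2, k_range[1] >= 2, k_range[1] <= k_range[2])
  sf <- standardize_features(table, policy = policy)
  pca <- fit_pca(sf)
  rows <- list()
  labels_list <- list()
  for (p in seq_len(pca$n_components)) {
    pts <- pca$scores[, seq_len(p), drop = FALSE]
    kseed <- as.integer(seed + 101L * p)
    k <- elbow_k(pts, k_min = k_range[1], k_max = k_range[2],
                 seed = kseed, nstart = nstart)
    if (is.na(k)) next
    fit <- cluster_kmeans(pts, k, seed = kseed + 1L, nstart = nstart)
    sil <- silhouette_avg(pts, fit$labels)
    fl <- filter_outlier_clusters(fit$labels, min_size = min_cluster_size)
    rows[[length(rows) + 1]] <- tibble::tibble(
      n_pcs = p, silhouette = sil, k = k,
      n_retained_clusters = nrow(fl$retained),
      n_retained_samples = sum(fl$retained$size),
      retained_sizes = paste(
        sprintf("%d(c-%d)", fl$retained$size, fl$retained$cluster),
        collapse = ", ")
    )
    labels_list[[as.character(p)]] <- fl$labels
  }
  tbl <- purrr::list_rbind(rows)
  if (nrow(tbl) == 0) {
    tbl <- tibble::tibble(scenario = integer(), n_pcs = integer(),
                          silhouette = double(), k = integer(),
                          n_retained_clusters = integer(),
                          n_retained_samples = integer(),
                          retained_sizes = character())
  } else {
    tbl <- dplyr::arrange(tbl, dplyr::desc(.data$silhouette), .data$n_pcs)
    tbl <- dplyr::mutate(tbl, scenario = dplyr::row_number(),
                         .before = "n_pcs")
  }
  structure(tbl,
            class = c("scenario_table", class(tibble::tibble())),
            labels = labels_list,
            pca = pca,
            standardized = sf,
            params = list(k_range = k_range,
                          min_cluster_size = min_cluster_size,
                          seed = seed, nstart = nstart, policy = policy))
}

#' Per-sample labels of one scenario
#'
#' @param scenarios A `scenario_table` from [enumerate_scenarios()].
#' @param scenario Scenario number (row of the sorted table).
#' @return Named integer vector of 0-based cluster ids, `NA` for samples in
#'   discarded outlier clusters.
#' @export
scenario_labels <- function(scenarios, scenario = 1) {
  stopifnot(inherits(scenarios, "scenario_table"))
  row <- scenarios[scenarios$scenario == scenario, ]
  if (nrow(row) != 1) stop("no scenario ", scenario, call. = FALSE)
  attr(scenarios, "labels")[[as.character(row$n_pcs)]]
}

#' Select the scenario for further analysis
#'
#' Picks the highest-silhouette scenario, optionally the best one whose
#' retained-cluster count does not exceed `max_retained_clusters` (the usual
#' preference for a low number of clusters).
#'
#' @inheritParams scenario_labels
#' @param max_retained_clusters Optional cap on the number of retained
#'   clusters.
#' @return An object of class `cluster_scenario`: list with `scenario`,
#'   `n_pcs`, `k`, `silhouette`, `labels` (named, `NA` = outlier),
#'   `retained` (tibble `cluster`, `size`), `importance` (the
#'   feature-by-component PCA importance matrix for this scenario's
#'   components) and `features` (the imputed, unscaled feature matrix).
#' @export
select_scenario <- function(scenarios, max_retained_clusters = NULL) {
  stopifnot(inherits(scenarios, "scenario_table"))
  if (nrow(scenarios) == 0) stop("empty scenario table", call. = FALSE)
  tbl <- scenarios
  if (!is.null(max_retained_clusters)) {
    tbl <- tbl[tbl$n_retained_clusters <= max_retained_clusters, ]
    if (nrow(tbl) == 0) {
      stop("no scenario with at most ", max_retained_clusters,
           " retained clusters", call. = FALSE)
    }
  }
  row <- tbl[1, ]
  labels <- scenario_labels(scenarios, row$scenario)
  sizes <- table(labels[!is.na(labels)])
  pca <- attr(scenarios, "pca")
  structure(
    list(
      scenario = row$scenario, n_pcs = row$n_pcs, k = row$k,
      silhouette = row$silhouette,
      labels = labels,
      retained = tibble::tibble(cluster = as.integer(names(sizes)),
                                size = as.integer(sizes)),
      importance = pca_feature_importance(pca, n_pcs = row$n_pcs),
      features = attr(scenarios, "standardized")$imputed
    ),
    class = "cluster_scenario"
  )
}

#' @export
print.cluster_scenario <- function(x, ...) {
  cat(sprintf(
    "<cluster_scenario> #%d: %d PC(s), k = %d, silhouette %.3f; retained %s\n",
    x$scenario, x$n_pcs, x$k, x$silhouette,
    paste(sprintf("%d(c-%d)", x$retained$size, x$retained$cluster),
          collapse = ", ")))
  invisible(x)
}
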