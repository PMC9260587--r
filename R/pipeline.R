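# End-to-end orchestration: configuration, the full discovery pipeline, and
# file writers for its outputs.

#' Pipeline configuration
#'
#' Collects every tunable of the discovery pipeline in one auditable object;
#' all defaults are documented here and echoed into every output for
#' provenance. Round-trips losslessly through JSON
#' ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param arena An [arena_config()].
#' @param qc_threshold Minimum mean detection confidence for a trial to enter
#'   the analysis (strictly above; default 0.70).
#' @param max_gap Maximum detection gap, in frames, filled by interpolation.
#' @param smooth_window Moving-average smoothing window (odd, frames).
#' @param onset_band Approach-onset outer band in pixels; `NULL` =
#'   `2 * stranger_radius`.
#' @param k_range Candidate k range for the elbow method.
#' @param min_cluster_size Clusters smaller than this are discarded as
#'   outliers.
#' @param seed Master seed for all randomized steps.
#' @param never_approached Missing-value policy for never-approached trials
#'   (see [compute_features()]).
#' @param impute_policy Missing-value policy for [standardize_features()].
#' @param max_retained_clusters Optional cap used by [select_scenario()].
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(arena = arena_config(), qc_threshold = 0.70,
                            max_gap = 5, smooth_window = 5, onset_band = NULL,
                            k_range = c(2, 10), min_cluster_size = 5,
                            seed = 1, never_approached = "censor",
                            impute_policy = "mean_impute",
                            max_retained_clusters = NULL) {
  stopifnot(inherits(arena, "arena_config"),
            qc_threshold >= 0, qc_threshold <= 1)
  structure(
    list(arena = arena, qc_threshold = qc_threshold, max_gap = max_gap,
         smooth_window = smooth_window, onset_band = onset_band,
         k_range = k_range, min_cluster_size = min_cluster_size,
         seed = as.integer(seed), never_approached = never_approached,
         impute_policy = impute_policy,
         max_retained_clusters = max_retained_clusters),
    class = "pipeline_config"
  )
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$arena <- unclass(out$arena)
  out
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the JSON serialization.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(config_as_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- obj$arena
  arena <- arena_config(width = a$width, height = a$height, fps = a$fps,
                        stranger_center = a$stranger_center,
                        stranger_radius = a$stranger_radius,
                        contact_threshold = a$contact_threshold,
                        trial_duration = a$trial_duration)
  pipeline_config(
    arena = arena, qc_threshold = obj$qc_threshold, max_gap = obj$max_gap,
    smooth_window = obj$smooth_window, onset_band = obj$onset_band,
    k_range = obj$k_range, min_cluster_size = obj$min_cluster_size,
    seed = obj$seed, never_approached = obj$never_approached,
    impute_policy = obj$impute_policy,
    max_retained_clusters = obj$max_retained_clusters
  )
}

# stable hash of the configuration, stamped into outputs for provenance
config_hash <- function(config) {
  s <- jsonlite::toJSON(config_as_list(config), auto_unbox = TRUE, digits = NA)
  # FNV-1a over the serialized config; cheap, dependency-free, stable
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full pattern-discovery pipeline
#'
#' QC-filters trials on mean detection confidence, preprocesses tracks (gap
#' interpolation, smoothing), builds the feature table, enumerates PCA /
#' k-means clustering scenarios, selects the best scenario by silhouette,
#' screens candidate features by PCA-loading importance, derives the
#' explanatory-feature patterns of the retained clusters, and — when an
#' external score table is supplied — compares clusters on each score with a
#' Mann-Whitney test.
#'
#' @param trials List of raw [tracked_trial()] objects.
#' @param scores Optional external score table (data frame with `trial_id`
#'   and numeric score columns).
#' @param config A [pipeline_config()].
#' @return An object of class `pattern_discovery`: list with `qc` (QC log),
#'   `features` (feature table), `scenarios` (`scenario_table`), `selected`
#'   (`cluster_scenario`), `candidates`, `report` (`pattern_report`),
#'   `score_comparison` (or `NULL`), and `config`.
#' @export
run_pipeline <- function(trials, scores = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  qc <- qc_filter_trials(trials, threshold = config$qc_threshold)
  if (length(qc$retained) < 4) {
    stop("fewer than 4 trials passed QC", call. = FALSE)
  }
  pre <- preprocess_trials(qc$retained, max_gap = config$max_gap,
                           window = config$smooth_window)
  features <- build_feature_table(pre, onset_band = config$onset_band,
                                  never_approached = config$never_approached)
  scenarios <- enumerate_scenarios(
    features, k_range = config$k_range,
    min_cluster_size = config$min_cluster_size, seed = config$seed,
    policy = config$impute_policy)
  if (nrow(scenarios) == 0) {
    stop("no clustering scenario produced an elbow k", call. = FALSE)
  }
  selected <- select_scenario(scenarios, config$max_retained_clusters)
  candidates <- candidate_features(selected$importance)
  cs <- cluster_set(selected$features, selected$labels)
  report <- explanatory_features(cs, candidates = candidates,
                                 importance = selected$importance,
                                 scenario = selected$scenario)
  comparison <- if (!is.null(scores)) {
    compare_external_scores(selected$labels, scores)
  }
  structure(
    list(qc = qc$log, features = features, scenarios = scenarios,
         selected = selected, candidates = candidates, report = report,
         score_comparison = comparison, config = config),
    class = "pattern_discovery"
  )
}

#' @export
print.pattern_discovery <- function(x, ...) {
  cat(sprintf("<pattern_discovery> %d/%d trials passed QC; %d scenario(s)\n",
              sum(x$qc$retained), nrow(x$qc), nrow(x$scenarios)))
  print(x$selected)
  cat(paste0("  ", render_patterns(x$report), collapse = "\n"), "\n")
  if (!is.null(x$score_comparison) && nrow(x$score_comparison$tests) > 0) {
    cat("External score tests (Mann-Whitney, two-sided):\n")
    print(x$score_comparison$tests)
  }
  invisible(x)
}

provenance_header <- function(config) {
  sprintf("# ethoclust config_hash=%s seed=%d", config_hash(config),
          config$seed)
}

#' Write the scenario table and per-scenario labels as CSV
#'
#' The scenario CSV has the columns `scenario`, `pc_num`, `silhouette`,
#' `cluster_num`, `filtered_cluster_num`, `num_samples`, `retained_sizes`;
#' the labels CSV has `trial_id`, `scenario`, `cluster` (empty = outlier).
#' Both start with a comment line carrying the config hash and seed.
#'
#' @param scenarios A `scenario_table`.
#' @param path Output CSV path for the scenario table.
#' @param labels_path Optional output CSV path for per-scenario labels.
#' @param config A [pipeline_config()], for the provenance header.
#' @return `path`, invisibly.
#' @export
write_scenario_csv <- function(scenarios, path, labels_path = NULL,
                               config = pipeline_config()) {
  stopifnot(inherits(scenarios, "scenario_table"))
  out <- tibble::tibble(
    scenario = scenarios$scenario, pc_num = scenarios$n_pcs,
    silhouette = round(scenarios$silhouette, 6),
    cluster_num = scenarios$k,
    filtered_cluster_num = scenarios$n_retained_clusters,
    num_samples = scenarios$n_retained_samples,
    retained_sizes = scenarios$retained_sizes)
  writeLines(provenance_header(config), path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  if (!is.null(labels_path)) {
    lab <- purrr::imap(attr(scenarios, "labels"), function(l, p) {
      sc <- scenarios$scenario[scenarios$n_pcs == as.integer(p)]
      tibble::tibble(trial_id = names(l), scenario = sc,
                     cluster = as.integer(l))
    }) |> purrr::list_rbind() |>
      dplyr::arrange(.data$scenario, .data$trial_id)
    writeLines(provenance_header(config), labels_path)
    readr::write_csv(lab, labels_path, append = TRUE, col_names = TRUE)
  }
  invisible(path)
}

#' Write a feature table as CSV with a parameter sidecar
#'
#' @param features Feature table from [build_feature_table()].
#' @param path Output CSV path; a JSON sidecar `<path>.params.json` records
#'   the configuration that produced the features.
#' @param config A [pipeline_config()].
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path, config = pipeline_config()) {
  out <- dplyr::mutate(features, dplyr::across(dplyr::where(is.numeric),
                                               ~ round(.x, 6)))
  writeLines(provenance_header(config), path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  jsonlite::write_json(config_as_list(config), paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a pattern report as text and JSON
#'
#' @param report A `pattern_report`.
#' @param path Output path for the text rendering.
#' @param json_path Optional output path for the JSON serialization.
#' @param config A [pipeline_config()].
#' @return `path`, invisibly.
#' @export
write_pattern_report <- function(report, path, json_path = NULL,
                                 config = pipeline_config()) {
  stopifnot(inherits(report, "pattern_report"))
  writeLines(c(provenance_header(config), render_patterns(report)), path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(scenario = report$scenario,
           clusters = report$clusters,
           candidates = report$candidates,
           patterns = report$patterns,
           directions = report$directions),
      json_path, auto_unbox = TRUE, digits = 8, null = "null")
  }
  invisible(path)
}
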