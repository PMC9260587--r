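# Candidate screening, directional counts, explanatory features, score tests.

two_cluster_set <- function(lo = c(1, 2), hi = c(9, 10), feature = "f1") {
  values <- matrix(c(lo, hi), ncol = 1,
                   dimnames = list(c("a", "b", "c", "d"), feature))
  labels <- c(a = 0L, b = 0L, c = 1L, d = 1L)
  cluster_set(values, labels)
}

test_that("importance is the absolute loading, matching the eigen oracle", {
  withr::with_seed(61, x <- scale(matrix(rnorm(120), 20, 6)))
  pca <- fit_pca(x)
  imp <- pca_feature_importance(pca)
  expect_true(all(imp >= 0))
  ev <- eigen(stats::cov(x))
  for (j in seq_len(ncol(imp))) {
    expect_equal(unname(imp[, j]), abs(ev$vectors[, j]), tolerance = 1e-8)
  }
  expect_identical(ncol(pca_feature_importance(pca, n_pcs = 2)), 2L)
})

test_that("candidate screening thresholds strictly at the per-component median", {
  imp <- matrix(c(0.9, 0.5, 0.1), ncol = 1,
                dimnames = list(c("a", "b", "c"), "PC1"))
  expect_identical(candidate_features(imp), "a")

  tie <- matrix(0.5, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  expect_length(candidate_features(tie), 0)

  # above the median on the second component only still qualifies
  imp2 <- matrix(c(0.5, 0.5, 0.5,
                   0.1, 0.2, 0.9), ncol = 2,
                 dimnames = list(c("a", "b", "c"), NULL))
  expect_identical(candidate_features(imp2), "c")

  # invariance under feature reordering
  withr::with_seed(62, big <- matrix(runif(33), 11, 3,
                                     dimnames = list(letters[1:11], NULL)))
  perm <- sample(11)
  expect_setequal(candidate_features(big), candidate_features(big[perm, ]))
})

test_that("directional counts follow the >= tie convention", {
  cs <- two_cluster_set()          # grand mean 5.5
  hi <- direction_counts(cs, "f1", 1)
  expect_identical(hi$H, 2L); expect_identical(hi$L, 0L)
  expect_identical(hi$direction, "up"); expect_identical(hi$support, 2L)
  lo <- direction_counts(cs, "f1", 0)
  expect_identical(lo$direction, "down"); expect_identical(lo$support, 2L)
  expect_identical(lo$H + lo$L, 2L)

  # samples exactly at the grand mean count as high
  cs2 <- two_cluster_set(lo = c(5.5, 5.5), hi = c(5.5, 5.5))
  at <- direction_counts(cs2, "f1", 0)
  expect_identical(at$H, 2L)
  expect_identical(at$direction, "up")

  expect_error(direction_counts(cs, "nope", 0), "unknown feature")
  expect_error(direction_counts(cs, "f1", 9), "unknown cluster")
})

test_that("direction flips when the feature is negated", {
  withr::with_seed(63, {
    for (rep in 1:10) {
      inst <- random_cluster_instance(3, 18, 2)
      cs_pos <- cluster_set(inst$values, inst$labels)
      cs_neg <- cluster_set(-inst$values, inst$labels)
      for (f in colnames(inst$values)) {
        for (cl in unique(inst$labels)) {
          d1 <- direction_counts(cs_pos, f, cl)
          d2 <- direction_counts(cs_neg, f, cl)
          # ignore boundary cases where a sample sits exactly at the mean
          vals <- inst$values[inst$labels == cl, f]
          if (any(abs(vals - mean(inst$values[, f])) < 1e-12)) next
          if (d1$direction == "up") expect_identical(d2$direction, "down")
          if (d1$direction == "down") expect_identical(d2$direction, "up")
        }
      }
    }
  })
})

test_that("the two-cluster worked example is explanatory in opposite directions", {
  cs <- two_cluster_set()
  rep <- explanatory_features(cs)
  expect_identical(nrow(rep$patterns), 2L)
  up <- rep$patterns[rep$patterns$cluster == 1, ]
  expect_identical(up$direction, "up")
  expect_identical(up$H, 2L); expect_identical(up$L, 0L)
  down <- rep$patterns[rep$patterns$cluster == 0, ]
  expect_identical(down$direction, "down")
  expect_error(explanatory_features(cluster_set(
    matrix(1:3, ncol = 1, dimnames = list(c("a", "b", "c"), "f")),
    c(a = 0L, b = 0L, c = 0L))), "at least 2")
})

test_that("a feature high in two of three clusters explains neither high cluster", {
  # f separates cluster 2 from the rest, so by the one-vs-all definition it
  # is down-explanatory for cluster 2 but explanatory for neither cluster
  # whose majority sits high (each fails to down-explain the other).
  values <- matrix(c(9, 10, 8, 9, 1, 2), ncol = 1,
                   dimnames = list(sprintf("s%d", 1:6), "f1"))
  labels <- stats::setNames(rep(0:2, each = 2), rownames(values))
  rep <- explanatory_features(cluster_set(values, labels))
  expect_identical(rep$patterns$cluster, 2L)
  expect_identical(rep$patterns$direction, "down")
  # and this is exactly what the exhaustive definition yields
  want <- oracle_explanatory(values, labels)
  expect_identical(nrow(want), 1L)
  expect_identical(want$cluster, 2L)

  # a feature whose majorities disagree non-uniformly explains nothing:
  # make the low group straddle the grand mean so no cluster is unanimous
  v2 <- matrix(c(9, 10, 8, 9, 1, 2, 3, 30), ncol = 1,
               dimnames = list(sprintf("s%d", 1:8), "f1"))
  l2 <- stats::setNames(rep(0:2, c(2, 2, 4)), rownames(v2))
  rep2 <- explanatory_features(cluster_set(v2, l2))
  expect_identical(nrow(rep2$patterns),
                   nrow(oracle_explanatory(v2, l2)))
})

test_that("explanatory features equal the exhaustive definition on random instances", {
  withr::with_seed(64, {
    for (rep_i in 1:40) {
      n_cl <- sample(2:5, 1)
      n <- sample((3 * n_cl):30, 1)
      p <- sample(1:11, 1)
      inst <- random_cluster_instance(n_cl, n, p)
      got <- tidy(explanatory_features(cluster_set(inst$values, inst$labels)))
      want <- oracle_explanatory(inst$values, inst$labels)
      got_key <- sort(sprintf("%s|%s|%s", got$cluster, got$feature,
                              got$direction))
      want_key <- sort(sprintf("%s|%s|%s", want$cluster, want$feature,
                               want$direction))
      expect_identical(got_key, want_key)
      # H + L = cluster size, always
      full <- explanatory_features(cluster_set(inst$values, inst$labels))
      sizes <- table(inst$labels)
      expect_true(all(full$directions$H + full$directions$L ==
                        as.integer(sizes[as.character(full$directions$cluster)])))
    }
  })
})

test_that("in a two-cluster set explanatory features pair with opposite directions", {
  withr::with_seed(65, {
    for (rep_i in 1:20) {
      inst <- random_cluster_instance(2, sample(6:24, 1), 3)
      rep <- explanatory_features(cluster_set(inst$values, inst$labels))
      for (f in unique(rep$patterns$feature)) {
        rows <- rep$patterns[rep$patterns$feature == f, ]
        expect_identical(nrow(rows), 2L)
        expect_setequal(rows$direction, c("up", "down"))
      }
    }
  })
})

test_that("pattern rendering is a fixed-order pure formatter", {
  cs <- two_cluster_set()
  rep <- explanatory_features(cs)
  lines <- render_patterns(rep)
  expect_identical(lines, c("Cluster 0 - Low f1", "Cluster 1 - High f1"))
  expect_identical(render_patterns(rep), lines)

  none <- explanatory_features(
    cluster_set(matrix(c(9, 1, 8, 2), ncol = 1,
                       dimnames = list(sprintf("s%d", 1:4), "f1")),
                stats::setNames(rep(0:1, each = 2), sprintf("s%d", 1:4))))
  expect_match(render_patterns(none), "no explanatory features", all = TRUE)
})

test_that("rank-sum comparison matches hand enumeration and a permutation null", {
  labels <- stats::setNames(rep(0:1, each = 3), sprintf("t%d", 1:6))
  scores <- tibble::tibble(trial_id = sprintf("t%d", 1:6),
                           s = c(1, 2, 3, 4, 5, 6))
  cmp <- compare_external_scores(labels, scores)
  expect_identical(nrow(cmp$descriptives), 2L)
  expect_equal(cmp$tests$statistic, 0)  # complete separation
  expect_equal(cmp$tests$statistic,
               oracle_u_statistic(c(1, 2, 3), c(4, 5, 6)))

  # identical groups: two-sided p ~ 1
  scores2 <- tibble::tibble(trial_id = sprintf("t%d", 1:6),
                            s = c(1, 2, 3, 1, 2, 3))
  cmp2 <- compare_external_scores(labels, scores2)
  expect_gt(cmp2$tests$p_value, 0.9)

  # exact p agrees with a full permutation null on a small 3-vs-4 split
  withr::with_seed(66, {
    vals <- rnorm(7)
    lab7 <- stats::setNames(rep(0:1, c(3, 4)), sprintf("t%d", 1:7))
    cmp3 <- compare_external_scores(
      lab7, tibble::tibble(trial_id = sprintf("t%d", 1:7), s = vals))
    u_obs <- oracle_u_statistic(vals[1:3], vals[4:7])
    combs <- utils::combn(7, 3)
    u_null <- apply(combs, 2, function(idx) {
      oracle_u_statistic(vals[idx], vals[-idx])
    })
    p_perm <- mean(abs(u_null - 6) >= abs(u_obs - 6))  # center = n1*n2/2
    expect_equal(cmp3$tests$p_value, p_perm, tolerance = 1e-9)
  })
})

test_that("more than two retained clusters gives descriptives only", {
  labels <- stats::setNames(rep(0:2, each = 3), sprintf("t%d", 1:9))
  scores <- tibble::tibble(trial_id = sprintf("t%d", 1:9), s = rnorm(9))
  expect_warning(cmp <- compare_external_scores(labels, scores),
                 "exactly 2")
  expect_identical(nrow(cmp$tests), 0L)
  expect_identical(nrow(cmp$descriptives), 3L)
})

test_that("missing scores are excluded pairwise with a logged count", {
  labels <- stats::setNames(rep(0:1, each = 4), sprintf("t%d", 1:8))
  scores <- tibble::tibble(trial_id = sprintf("t%d", 1:8),
                           s1 = c(NA, rnorm(7)), s2 = rnorm(8))
  expect_message(cmp <- compare_external_scores(labels, scores),
                 "excluding missing")
  expect_identical(cmp$n_missing$n_missing[cmp$n_missing$score == "s1"], 1L)
  expect_identical(sum(cmp$descriptives$n[cmp$descriptives$score == "s1"]), 7L)
})
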