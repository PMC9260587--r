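# Movement features and their geometric primitives.

test_that("contact predicate is inclusive at the boundary", {
  a <- toy_arena(1)                       # stranger (500,500), r 10, band 5
  expect_true(in_contact(500, 500, a))
  expect_true(in_contact(515, 500, a))    # exactly radius + threshold
  expect_false(in_contact(516, 500, a))
})

test_that("path length is additive and handles degenerate ranges", {
  tr <- make_trial(x = c(0, 3, 3), y = c(0, 0, 4), arena = toy_arena(3))
  expect_equal(path_length(tr), 7)
  expect_equal(path_length(tr, 2, 2), 0)
  expect_error(path_length(tr, 0, 2), "out of range")
  expect_error(path_length(tr, 3, 2), "out of range")

  set.seed(5)
  rnd <- make_trial(x = runif(50, 0, 100), y = runif(50, 0, 100),
                    arena = toy_arena(50))
  for (k in c(2, 17, 49)) {
    expect_equal(path_length(rnd, 1, k) + path_length(rnd, k, 50),
                 path_length(rnd, 1, 50), tolerance = 1e-12)
  }
})

test_that("convex hull area matches hand cases and an independent implementation", {
  expect_equal(convex_hull_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))), 1)
  expect_equal(convex_hull_area(cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))), 0)
  expect_equal(convex_hull_area(cbind(c(2, 2), c(3, 3))), 0)

  set.seed(9)
  for (rep in 1:5) {
    x <- runif(100, 0, 10); y <- runif(100, 0, 10)
    expect_equal(convex_hull_area(cbind(x, y)), oracle_hull_area(x, y),
                 tolerance = 1e-9)
  }
})

test_that("hull area is permutation/translation invariant and scales as s^2", {
  set.seed(13)
  x <- runif(30); y <- runif(30)
  base <- convex_hull_area(cbind(x, y))
  perm <- sample(30)
  expect_equal(convex_hull_area(cbind(x[perm], y[perm])), base)
  expect_equal(convex_hull_area(cbind(x + 55, y - 12)), base)
  s <- 3.7
  expect_equal(convex_hull_area(cbind(s * x, s * y)), s^2 * base,
               tolerance = 1e-9)
  # hence intensity of use is scale-invariant
  len <- path_length(tibble::tibble(x = x, y = y))
  expect_equal(intensity_of_use(s * len, convex_hull_area(cbind(s * x, s * y))),
               intensity_of_use(len, base), tolerance = 1e-9)
})

test_that("straightness matches hand computations", {
  straight <- make_trial(x = seq(0, 9), y = rep(0, 10), arena = toy_arena(10))
  expect_equal(straightness(straight$track), 1)
  lpath <- make_trial(x = c(0, 3, 3), y = c(0, 0, 4), arena = toy_arena(3))
  expect_equal(straightness(lpath$track), 5 / 7)
  loop <- make_trial(x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0),
                     arena = toy_arena(5))
  expect_equal(straightness(loop$track), 0)
  still <- make_trial(x = rep(2, 3), y = rep(2, 3), arena = toy_arena(3))
  expect_true(is.na(straightness(still$track)))
})

test_that("intensity of use is 4 for any square perimeter and NA on a degenerate hull", {
  for (s in c(1, 2.5, 117)) {
    sq <- tibble::tibble(x = c(0, s, s, 0, 0), y = c(0, 0, s, s, 0))
    expect_equal(intensity_of_use(path_length(sq), convex_hull_area(sq)), 4,
                 tolerance = 1e-12)
  }
  expect_true(is.na(intensity_of_use(10, 0)))
  expect_equal(intensity_of_use(0, 4), 0)
  expect_error(intensity_of_use(-1, 4), "non-negative")
})

test_that("contact stats count frames at the configured rate", {
  arena <- arena_config(fps = 30, trial_duration = 40)
  inside <- arena$stranger_center
  far <- c(10, 10)
  # 300 of 1200 frames in contact
  xs <- c(rep(inside[1], 300), rep(far[1], 900))
  ys <- c(rep(inside[2], 300), rep(far[2], 900))
  tr <- make_trial(x = xs, y = ys, frame = 0:1199, arena = arena)
  cs <- contact_stats(tr)
  expect_equal(cs$total_contact, 10)
  expect_equal(cs$contact_ratio, 0.25)

  all_in <- make_trial(x = rep(inside[1], 1200), y = rep(inside[2], 1200),
                       frame = 0:1199, arena = arena)
  expect_equal(contact_stats(all_in), list(total_contact = 40,
                                           contact_ratio = 1))
  none <- make_trial(x = rep(10, 1200), y = rep(10, 1200), frame = 0:1199,
                     arena = arena)
  expect_equal(contact_stats(none), list(total_contact = 0, contact_ratio = 0))
})

test_that("approach events match a brute-force frame scan", {
  arena <- arena_config(width = 1000, height = 1000, fps = 10,
                        stranger_center = c(500, 500), stranger_radius = 50,
                        contact_threshold = 50, trial_duration = 10)
  # walk straight from the corner to the stranger
  tr <- straight_trial(c(50, 950), c(500, 500), 100, arena)
  ev <- detect_approach_events(tr, onset_band = 100)
  d <- sqrt((tr$track$x - 500)^2 + (tr$track$y - 500)^2)
  i_A <- which(d <= 100)[1]
  expect_true(ev$approached)
  expect_identical(ev$i_A, as.integer(i_A))
  expect_equal(ev$t_A, tr$track$t[i_A])
  expect_identical(ev$i_onset, as.integer(max(which(d > 200 &
                                                    seq_along(d) < i_A))))
  expect_equal(ev$A, c(tr$track$x[i_A], tr$track$y[i_A]))

  # never in proximity
  far <- make_trial(x = seq(1, 50), y = rep(1, 50), arena = toy_arena(50))
  ev2 <- detect_approach_events(far)
  expect_false(ev2$approached)
  expect_null(ev2$A)

  # starts inside proximity: degenerate approach
  inside <- make_trial(x = rep(500, 5), y = rep(500, 5), arena = toy_arena(5))
  ev3 <- detect_approach_events(inside)
  expect_equal(ev3$t_A, 0)
  expect_equal(ev3$t_onset, 0)
})

test_that("a constant-speed straight approach yields closed-form features", {
  v <- 100 # px/s
  arena <- arena_config(width = 1000, height = 1000, fps = 10,
                        stranger_center = c(500, 500), stranger_radius = 50,
                        contact_threshold = 50, trial_duration = 5)
  # start 500 px left of the stranger, walk right at v px/s for 5 s
  n <- 50
  tr <- make_trial(x = seq(0, by = v / 10, length.out = n),
                   y = rep(500, n), frame = 0:(n - 1), arena = arena)
  f <- compute_features(tr, onset_band = 100)
  # contact circle entered at x = 400 -> after 400/v = 4 s
  expect_equal(f$time_until_approach, 4)
  expect_equal(f$straightness_until_first_approach, 1)
  expect_equal(f$speed_of_first_approach, v, tolerance = 1e-9)
  expect_equal(f$straightness, 1)
  expect_true(f$approached)
})

test_that("stationary and never-approaching trials follow the missing-value policy", {
  still <- make_trial(x = rep(10, 20), y = rep(10, 20), arena = toy_arena(20))
  f <- compute_features(still)
  expect_equal(f$trajectory_length, 0)
  expect_equal(f$total_contact, 0)
  expect_false(f$approached)
  expect_equal(f$time_until_approach, 20)   # censored at trial duration
  expect_true(is.na(f$duration_of_approach))
  expect_true(is.na(f$speed_of_first_approach))
  expect_true(is.na(f$intensity_of_use))    # degenerate hull

  f2 <- compute_features(still, never_approached = "drop")
  expect_true(is.na(f2$time_until_approach))
})

test_that("features agree with the frame-scan oracle on simulated trials", {
  for (i in 1:10) {
    params <- if (i %% 2 == 0) phenotype_approach_prone() else
      phenotype_avoidant()
    trial <- simulate_trial(params, seed = 100 + i,
                            trial_id = sprintf("s%d", i))
    got <- compute_features(trial)
    want <- oracle_features(trial)
    for (f in feature_names()) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9,
                   info = sprintf("trial %d, feature %s", i, f))
    }
    expect_identical(got$approached, want$approached)
    # invariant bounds
    if (got$approached) {
      expect_lte(got$trajectory_length_until_first_approach,
                 got$trajectory_length + 1e-9)
    }
    expect_lte(got$total_contact, trial$arena$trial_duration)
    ok_str <- !is.na(got$straightness)
    if (ok_str) expect_true(got$straightness >= 0 && got$straightness <= 1 + 1e-12)
    expect_equal(got$contact_ratio * nrow(trial$track),
                 round(got$contact_ratio * nrow(trial$track)))
  }
})

test_that("the feature table is one keyed row per trial with fixed columns", {
  cohort <- simulate_cohort(demo_cohort_spec(seed = 3, n_prone = 3,
                                             n_avoidant = 2))
  tbl <- build_feature_table(cohort$trials)
  expect_identical(nrow(tbl), 5L)
  expect_identical(names(tbl), c("trial_id", feature_names(), "approached"))
  expect_identical(tbl$trial_id, purrr::map_chr(cohort$trials, "trial_id"))

  single <- build_feature_table(cohort$trials[1])
  expect_identical(nrow(single), 1L)

  expect_error(build_feature_table(cohort$trials[c(1, 1)]), "duplicate")
})
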