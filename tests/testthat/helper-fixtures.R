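# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately written as naive, frame-by-frame or exhaustive
# computations, independent of the package's implementation paths.

# --- fixture builders -------------------------------------------------------

# small square arena; fps = 1 makes t == frame, handy for hand computation
toy_arena <- function(n_points, fps = 1, width = 1000, height = 1000,
                      stranger_center = c(500, 500), stranger_radius = 10,
                      contact_threshold = 5) {
  arena_config(width = width, height = height, fps = fps,
               stranger_center = stranger_center,
               stranger_radius = stranger_radius,
               contact_threshold = contact_threshold,
               trial_duration = n_points / fps)
}

make_trial <- function(x, y, frame = seq_along(x) - 1L, confidence = NA_real_,
                       arena = NULL, trial_id = "t1", fps = 1) {
  if (is.null(arena)) arena <- toy_arena(max(frame) + 1, fps = fps)
  tracked_trial(trial_id,
                tibble::tibble(frame = frame, x = x, y = y,
                               confidence = confidence),
                arena)
}

# straight constant-speed walk from `from` toward `to`, n points, fps frames/s
straight_trial <- function(from, to, n, arena, trial_id = "straight") {
  w <- seq(0, 1, length.out = n)
  make_trial(x = from[1] + w * (to[1] - from[1]),
             y = from[2] + w * (to[2] - from[2]),
             frame = seq_len(n) - 1L, arena = arena, trial_id = trial_id)
}

# --- geometry oracles -------------------------------------------------------

# Convex hull area via Andrew's monotone chain + trapezoid integration of the
# upper/lower envelopes; shares no code with the package's chull/shoelace path.
oracle_hull_area <- function(x, y) {
  pts <- unique(data.frame(x = x, y = y))
  pts <- pts[order(pts$x, pts$y), ]
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b) {
    (a$x - o$x) * (b$y - o$y) - (a$y - o$y) * (b$x - o$x)
  }
  build <- function(idx) {
    hull <- integer(0)
    for (i in idx) {
      while (length(hull) >= 2 &&
             cross(pts[hull[length(hull) - 1], ], pts[hull[length(hull)], ],
                   pts[i, ]) <= 0) {
        hull <- hull[-length(hull)]
      }
      hull <- c(hull, i)
    }
    hull
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  poly <- c(lower[-length(lower)], upper[-length(upper)])  # closed hull walk
  xs <- pts$x[poly]; ys <- pts$y[poly]
  xs2 <- c(xs[-1], xs[1]); ys2 <- c(ys[-1], ys[1])
  abs(sum((xs2 - xs) * (ys2 + ys) / 2))  # trapezoid integral around the walk
}

# --- feature oracle: naive frame-by-frame scan ------------------------------

oracle_features <- function(trial, onset_band = NULL) {
  a <- trial$arena
  if (is.null(onset_band)) onset_band <- 2 * a$stranger_radius
  tr <- trial$track
  n <- nrow(tr)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- sqrt((tr$x[i] - a$stranger_center[1])^2 +
                 (tr$y[i] - a$stranger_center[2])^2)
  }
  contact_r <- a$stranger_radius + a$contact_threshold
  contact <- d <= contact_r
  seg <- function(i, j) {
    total <- 0
    if (j > i) for (k in i:(j - 1)) {
      total <- total + sqrt((tr$x[k + 1] - tr$x[k])^2 +
                            (tr$y[k + 1] - tr$y[k])^2)
    }
    total
  }
  chord <- function(i, j) sqrt((tr$x[j] - tr$x[i])^2 + (tr$y[j] - tr$y[i])^2)
  total_len <- seg(1, n)
  hull <- oracle_hull_area(tr$x, tr$y)
  n_contact <- sum(contact)
  i_A <- if (any(contact)) which(contact)[1] else NA_integer_
  approached <- !is.na(i_A)
  if (approached) {
    i_onset <- 1L
    for (i in seq_len(n)) {
      if (i < i_A && d[i] > contact_r + onset_band) i_onset <- i
    }
    t_A <- tr$t[i_A]
    t_onset <- if (i_A == 1) 0 else tr$t[i_onset]
    dur <- t_A - t_onset
    list(
      time_until_approach = t_A,
      duration_of_approach = dur,
      speed_of_first_approach = if (dur > 0) seg(i_onset, i_A) / dur else NA_real_,
      trajectory_length = total_len,
      trajectory_length_until_first_approach = seg(1, i_A),
      area = hull,
      intensity_of_use = if (hull > 0) total_len / sqrt(hull) else NA_real_,
      total_contact = n_contact / a$fps,
      straightness = if (total_len > 0) chord(1, n) / total_len else NA_real_,
      straightness_until_first_approach =
        if (i_A > 1 && seg(1, i_A) > 0) chord(1, i_A) / seg(1, i_A)
        else NA_real_,
      contact_ratio = n_contact / n,
      approached = TRUE
    )
  } else {
    list(
      time_until_approach = a$trial_duration,
      duration_of_approach = NA_real_,
      speed_of_first_approach = NA_real_,
      trajectory_length = total_len,
      trajectory_length_until_first_approach = NA_real_,
      area = hull,
      intensity_of_use = if (hull > 0) total_len / sqrt(hull) else NA_real_,
      total_contact = 0,
      straightness = if (total_len > 0) chord(1, n) / total_len else NA_real_,
      straightness_until_first_approach = NA_real_,
      contact_ratio = 0,
      approached = FALSE
    )
  }
}

# --- silhouette oracle: per-sample a(i)/b(i), straight from the definition --

oracle_silhouette <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a_i <- mean(d[i, setdiff(own, i)])
    b_i <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

# --- explanatory-feature oracle: literal exhaustive evaluation --------------

# values: samples x features matrix; labels: cluster id per sample.
# Returns a data.frame of (cluster, feature, direction) triples, evaluating
# the definition directly: H = #{c in C : c_f >= grand mean}, up-explanatory
# iff H > L in C and L > H in every other cluster (dually for down).
oracle_explanatory <- function(values, labels, candidates = colnames(values)) {
  clusters <- sort(unique(labels))
  out <- list()
  for (f in candidates) {
    gm <- mean(values[, f])
    hl <- lapply(clusters, function(cl) {
      v <- values[labels == cl, f]
      c(H = sum(v >= gm), L = sum(v < gm))
    })
    names(hl) <- as.character(clusters)
    for (cl in clusters) {
      own <- hl[[as.character(cl)]]
      others <- hl[as.character(setdiff(clusters, cl))]
      up <- own["H"] > own["L"] &&
        all(vapply(others, function(o) o["L"] > o["H"], logical(1)))
      down <- own["L"] > own["H"] &&
        all(vapply(others, function(o) o["H"] > o["L"], logical(1)))
      if (up || down) {
        out[[length(out) + 1]] <- data.frame(
          cluster = cl, feature = f, direction = if (up) "up" else "down")
      }
    }
  }
  if (length(out) == 0) {
    data.frame(cluster = integer(), feature = character(),
               direction = character())
  } else {
    do.call(rbind, out)
  }
}

# random cluster-set instance for the exhaustive equivalence checks
random_cluster_instance <- function(n_clusters, n_samples, n_features) {
  labels <- sample(rep(seq_len(n_clusters) - 1L, length.out = n_samples))
  values <- matrix(stats::rnorm(n_samples * n_features), n_samples,
                   dimnames = list(sprintf("s%d", seq_len(n_samples)),
                                   sprintf("f%d", seq_len(n_features))))
  list(values = values, labels = stats::setNames(labels, rownames(values)))
}

# --- rank-sum oracle: permutation null of the U statistic -------------------

oracle_u_statistic <- function(g1, g2) {
  sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
}
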