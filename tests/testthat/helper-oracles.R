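# Shared fixtures and independent brute-force oracles used across tests.

melt_grid <- function(from = 25, to = 60, by = 0.5) seq(from, to, by)

quench_concs <- c(0, 1, 3, 5, 8, 10, 15, 20, 25, 30, 35, 40, 45, 50, 75, 100)

# Grid-search oracle for the monophasic melt midpoint: exhaustive scan over
# (Tm, w) with baselines/amplitude solved by linear least squares at each
# grid point. Independent of the package's optimizer.
grid_search_tm <- function(temperature, fluorescence,
                           tm_range = range(temperature), tm_step = 0.01,
                           w_grid = seq(0.4, 3, 0.1)) {
  tms <- seq(tm_range[1], tm_range[2], tm_step)
  best <- c(Inf, NA)
  for (w in w_grid) {
    for (tm in tms) {
      s <- 1 / (1 + exp((tm - temperature) / w))
      fit <- stats::lm.fit(cbind(1, s), fluorescence)
      rss <- sum(fit$residuals^2)
      if (rss < best[1]) best <- c(rss, tm)
    }
  }
  best[2]
}

# Two-transition variant: coarse exhaustive search over (tm1, tm2) pairs
# with shared width and linearly solved amplitudes.
grid_search_tm2 <- function(temperature, fluorescence, step = 0.05, w = 1) {
  tms <- seq(min(temperature) + 2, max(temperature) - 2, step)
  best <- c(Inf, NA, NA)
  for (i in seq_along(tms)) {
    s1 <- 1 / (1 + exp((tms[i] - temperature) / w))
    for (j in seq_along(tms)) {
      if (tms[j] <= tms[i] + 4) next
      s2 <- 1 / (1 + exp((tms[j] - temperature) / w))
      fit <- stats::lm.fit(cbind(1, s1, s2), fluorescence)
      rss <- sum(fit$residuals^2)
      if (rss < best[1]) best <- c(rss, tms[i], tms[j])
    }
  }
  best[2:3]
}

# Brute-force MM grid search over (Km, Vmax).
grid_search_mm <- function(s, v, km_grid, vmax_grid) {
  best <- c(Inf, NA, NA)
  for (km in km_grid) {
    pred_base <- s / (km + s)
    for (vm in vmax_grid) {
      rss <- sum((v - vm * pred_base)^2)
      if (rss < best[1]) best <- c(rss, km, vm)
    }
  }
  best[2:3]
}

# Naive reference for sphere-exclusion clustering, written independently of
# cluster_library(): explicit pairwise loops, no matrix algebra.
reference_cluster <- function(fps, threshold) {
  n <- nrow(fps)
  sim <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    inter <- sum(fps[a, ] & fps[b, ])
    un <- sum(fps[a, ] | fps[b, ])
    sim[a, b] <- if (un == 0) 0 else inter / un
  }
  assigned <- rep(NA_integer_, n)
  cl <- 0L
  repeat {
    open <- which(is.na(assigned))
    if (!length(open)) break
    counts <- sapply(open, function(j)
      sum(sim[j, open] >= threshold) - 1L)
    leader <- open[which.max(counts)]
    cl <- cl + 1L
    for (j in open) if (sim[leader, j] >= threshold) assigned[j] <- cl
    assigned[leader] <- cl
  }
  assigned
}

random_fps <- function(n, bits = 64, seed = 1, density = 0.3) {
  set.seed(seed)
  matrix(rbinom(n * bits, 1, density), nrow = n)
}

# Random typed pose features around (or away from) model points.
random_pose <- function(model_points, spread = 3) {
  data.frame(
    feature_type = sample(c("HBA", "hydrophobic"), nrow(model_points),
                          replace = TRUE),
    x = model_points$x + rnorm(nrow(model_points), 0, spread),
    y = model_points$y + rnorm(nrow(model_points), 0, spread),
    z = model_points$z + rnorm(nrow(model_points), 0, spread))
}

# Brute-force pharmacophore satisfaction count.
brute_pharmacophore_count <- function(pose, points) {
  count <- 0L
  for (j in seq_len(nrow(points))) {
    ok <- FALSE
    for (i in seq_len(nrow(pose))) {
      if (pose$feature_type[i] != points$feature_type[j]) next
      d <- sqrt((pose$x[i] - points$x[j])^2 + (pose$y[i] - points$y[j])^2 +
                  (pose$z[i] - points$z[j])^2)
      if (d <= points$radius[j]) { ok <- TRUE; break }
    }
    if (ok) count <- count + 1L
  }
  count
}

example_pharmacophore <- function(radius = 1.5) {
  pharmacophore_model(data.frame(
    feature_type = c("HBA", "hydrophobic", "hydrophobic", "hydrophobic"),
    x = c(0, 4, -3, 2), y = c(0, 1, 2, -4), z = c(0, -2, 1, 3),
    radius = radius))
}
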