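# Shared fixtures and independent oracles for the test suite.

# small random volume on a seeded grid
rand_volume <- function(dims = c(8L, 8L, 8L), seed = 1L, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), direction = diag(3)) {
  set.seed(seed)
  lab_volume(array(rnorm(prod(dims)), dims), spacing, origin, direction)
}

# random rigid transform with bounded rotation (deg) and translation (mm)
rand_rigid <- function(seed, max_deg = 30, max_mm = 10, center = c(0, 0, 0)) {
  set.seed(seed)
  ang <- runif(3, -max_deg, max_deg) * pi / 180
  rigid_transform(euler_rotation(ang[1], ang[2], ang[3]),
                  runif(3, -max_mm, max_mm), center)
}

rand_triplet <- function(seed) {
  set.seed(seed)
  repeat {
    pts <- matrix(runif(9, -20, 20), 3, 3)
    tri <- tryCatch(landmark_triplet(pts[, 1], pts[, 2], pts[, 3]),
                    error = function(e) NULL)
    if (!is.null(tri)) return(tri)
    pts <- pts + rnorm(9)
  }
}

# a small phantom spec that fits fast unit tests
small_spec <- function(...) phantom_spec(grid_size = c(40L, 40L, 40L), ...)

# quick registration settings for tests that exercise the engine mechanics
# rather than its accuracy
quick_reg_config <- function(...) {
  registration_config(pyramid = list(c(2, 1), c(1, 0)),
                      max_iterations = 100L, init_search_deg = 0, ...)
}

# --- independent oracles --------------------------------------------------

# Costes sweep by definition: for every candidate T (distinct ch1 values,
# descending), Pearson r of voxels below both thresholds; first T with
# r <= 0 wins, else the minimum observed ch1.
oracle_costes_T1 <- function(x, y) {
  fit <- stats::prcomp(cbind(x, y))  # TLS line via PCA
  a <- fit$rotation[2, 1] / fit$rotation[1, 1]
  b <- mean(y) - a * mean(x)
  if (stats::cor(x, y) <= 0) return(max(x))
  for (T in sort(unique(x), decreasing = TRUE)) {
    sub <- x < T & y < a * T + b
    if (sum(sub) >= 3 && stats::var(x[sub]) > 0 && stats::var(y[sub]) > 0 &&
        stats::cor(x[sub], y[sub]) <= 0) {
      return(T)
    }
  }
  min(x)
}

# Kendall tau-b by O(n^2) pair enumeration
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Euclidean-ball lattice points within radius r of the origin
oracle_ball_count <- function(r) {
  off <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  sum(off$x^2 + off$y^2 + off$z^2 <= r^2 + 1e-9)
}

# landmark TRE of a recovered transform against truth correspondence
tre_mm <- function(transform, subject_lm, atlas_lm) {
  mapped <- transform_points(transform, landmark_matrix(subject_lm))
  mean(sqrt(colSums((mapped - landmark_matrix(atlas_lm))^2)))
}
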