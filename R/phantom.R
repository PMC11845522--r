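# Synthetic labyrinth phantom: analytic solid geometry (three partial
# semicircular-canal tori, a vestibule ellipsoid, a conical cochlear spiral
# tube) rasterized from signed distance at voxel centers, posed rigidly,
# blurred and corrupted by seeded noise. Stands in for patient MRI and the
# atlas in all end-to-end tests.

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stopf("zero-length direction vector")
  v / n
}

# orthonormal in-plane basis for a unit normal
plane_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize3(cross3(ref, n))
  v <- cross3(n, u)
  list(u = u, v = v)
}

#' Specification of a synthetic labyrinth phantom
#'
#' Describes the analytic geometry and imaging model of one phantom: a
#' bright fluid-filled labyrinth (three near-orthogonal partial
#' semicircular-canal tori, a vestibule ellipsoid, a conical cochlear
#' spiral) on a darker tissue background, with a rigid pose, Gaussian
#' smoothing, seeded additive Gaussian noise, and an optional large bright
#' distractor structure (brainstem-like) that is *not* moved by the pose —
#' exactly the situation in which an unmasked similarity metric is pulled
#' away from the labyrinth.
#'
#' @param grid_size Integer length-3 voxel grid (default 64^3).
#' @param spacing_mm Voxel size in mm (default 0.5 isotropic).
#' @param canal_torus_radii_mm Major radii of the posterior, superior and
#'   lateral canal tori (mm).
#' @param canal_tube_radius_mm Canal lumen tube radius (mm).
#' @param canal_normals 3x3 matrix, columns = unit plane normals of the
#'   three canals (must be pairwise within 90 +/- 20 degrees).
#' @param canal_arc_deg Angular extent of each canal arc (degrees).
#' @param vestibule_semiaxes_mm Ellipsoid semi-axes (mm).
#' @param cochlea_turns,cochlea_base_radius_mm,cochlea_height_mm,cochlea_tube_radius_mm
#'   Conical-spiral parameters of the cochlea.
#' @param fluid_intensity,background_intensity Intensities of labyrinth
#'   fluid and background tissue (fluid must be brighter).
#' @param background_texture_amp Amplitude of the smooth deterministic
#'   tissue texture superimposed on the background (0 = flat background).
#'   The texture is part of the anatomy: it moves with the pose, like the
#'   trabecular pattern of the petrous bone around a real labyrinth.
#' @param smoothing_sigma_mm Gaussian blur applied after rasterization.
#' @param noise_sd Additive Gaussian noise SD (0 = noise-free).
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param chirality `"right"` (default) or `"left"` (mirrored pair).
#' @param pose A [rigid_transform()] moving the labyrinth within the grid.
#' @param distractor Optional list `(center_mm, radius_mm, intensity)`; the
#'   distractor stays fixed in grid space regardless of `pose`.
#' @param seed Integer noise seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(64L, 64L, 64L),
                         spacing_mm = 0.5,
                         canal_torus_radii_mm = c(3.2, 3.0, 2.8),
                         canal_tube_radius_mm = 0.8,
                         canal_normals = cbind(
                           normalize3(c(1, -1, 0)),
                           normalize3(c(1, 1, 0)),
                           normalize3(c(0, sin(pi / 9), cos(pi / 9)))),
                         canal_arc_deg = 250,
                         vestibule_semiaxes_mm = c(2.4, 1.8, 1.6),
                         cochlea_turns = 2,
                         cochlea_base_radius_mm = 2,
                         cochlea_height_mm = 2.5,
                         cochlea_tube_radius_mm = 0.65,
                         fluid_intensity = 100,
                         background_intensity = 10,
                         background_texture_amp = 4,
                         smoothing_sigma_mm = 0.3,
                         noise_sd = 2,
                         noise_model = c("gaussian", "rician"),
                         chirality = c("right", "left"),
                         pose = rigid_transform(),
                         distractor = NULL,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  chirality <- match.arg(chirality)
  stopifnot(length(grid_size) == 3L, all(grid_size >= 8L),
            is_scalar_number(spacing_mm), spacing_mm > 0,
            length(canal_torus_radii_mm) == 3L, all(canal_torus_radii_mm > 0),
            canal_tube_radius_mm > 0, all(vestibule_semiaxes_mm > 0),
            cochlea_turns > 0, cochlea_base_radius_mm > 0,
            cochlea_height_mm > 0, cochlea_tube_radius_mm > 0,
            noise_sd >= 0, background_texture_amp >= 0,
            is_rigid_transform(pose))
  if (fluid_intensity <= background_intensity) {
    stopf("fluid intensity must exceed background intensity")
  }
  canal_normals <- apply(canal_normals, 2, normalize3)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    ang <- acos(min(1, abs(sum(canal_normals[, pair[1]] *
                               canal_normals[, pair[2]])))) * 180 / pi
    if (ang < 70) {
      stopf("canal planes %d and %d meet at %.0f deg; canals must be near-orthogonal (90 +/- 20 deg)",
            pair[1], pair[2], ang)
    }
  }
  if (!is.null(distractor)) {
    stopifnot(is.list(distractor),
              all(c("center_mm", "radius_mm", "intensity") %in% names(distractor)),
              distractor$radius_mm > 0)
  }
  structure(list(grid_size = as.integer(grid_size), spacing_mm = spacing_mm,
                 canal_torus_radii_mm = canal_torus_radii_mm,
                 canal_tube_radius_mm = canal_tube_radius_mm,
                 canal_normals = canal_normals,
                 canal_arc_deg = canal_arc_deg,
                 vestibule_semiaxes_mm = vestibule_semiaxes_mm,
                 cochlea_turns = cochlea_turns,
                 cochlea_base_radius_mm = cochlea_base_radius_mm,
                 cochlea_height_mm = cochlea_height_mm,
                 cochlea_tube_radius_mm = cochlea_tube_radius_mm,
                 fluid_intensity = fluid_intensity,
                 background_intensity = background_intensity,
                 background_texture_amp = background_texture_amp,
                 smoothing_sigma_mm = smoothing_sigma_mm,
                 noise_sd = noise_sd, noise_model = noise_model,
                 chirality = chirality, pose = pose,
                 distractor = distractor, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Internal geometry description in unposed (atlas) space, centered on the
# grid center of the spec.
phantom_geometry <- function(spec) {
  ctr <- (spec$grid_size - 1) / 2 * spec$spacing_mm
  canal_centers <- cbind(ctr + c(1.2, -1.2, 0.2),    # posterior
                         ctr + c(1.2, 1.2, 0.8),     # superior
                         ctr + c(0.8, 0.2, -0.8))    # lateral
  vest_center <- ctr + c(0.5, 0, -0.5)
  cochlea_center <- ctr + c(-2.6, 2.2, -1.8)
  cochlea_axis <- normalize3(c(-0.5, 0.6, -0.6))
  list(ctr = ctr, canal_centers = canal_centers, vest_center = vest_center,
       cochlea_center = cochlea_center, cochlea_axis = cochlea_axis)
}

# Vertices of the cochlear spiral polyline in unposed space.
cochlea_curve <- function(spec, geom, n = 120L) {
  b <- plane_basis(geom$cochlea_axis)
  t <- seq(0, 1, length.out = n)
  th <- 2 * pi * spec$cochlea_turns * t
  rho <- spec$cochlea_base_radius_mm * (1 - 0.85 * t)
  verts <- geom$cochlea_center +
    outer(b$u, rho * cos(th)) + outer(b$v, rho * sin(th)) +
    outer(geom$cochlea_axis, spec$cochlea_height_mm * t)
  verts
}

# Signed distance of the full labyrinth at points (3 x n, unposed space).
labyrinth_sdf <- function(spec, geom, pts) {
  n <- ncol(pts)
  sdf <- rep(Inf, n)
  gap_half <- (360 - spec$canal_arc_deg) / 2 * pi / 180
  for (ci in 1:3) {
    cc <- geom$canal_centers[, ci]
    nn <- spec$canal_normals[, ci]
    R <- spec$canal_torus_radii_mm[ci]
    rt <- spec$canal_tube_radius_mm
    bas <- plane_basis(nn)
    q <- pts - cc
    qn <- colSums(q * nn)
    qu <- colSums(q * bas$u)
    qv <- colSums(q * bas$v)
    rad <- sqrt(qu^2 + qv^2)
    # gap faces the vestibule
    gdir <- geom$vest_center - cc
    gproj <- c(sum(gdir * bas$u), sum(gdir * bas$v))
    gang <- atan2(gproj[2], gproj[1])
    dth <- atan2(qv, qu) - gang
    dth <- atan2(sin(dth), cos(dth))        # wrap to (-pi, pi]
    on_arc <- abs(dth) >= gap_half
    d_torus <- sqrt((rad - R)^2 + qn^2) - rt
    # end caps: spheres at the two arc endpoints
    e1 <- cc + R * (cos(gang + gap_half) * bas$u + sin(gang + gap_half) * bas$v)
    e2 <- cc + R * (cos(gang - gap_half) * bas$u + sin(gang - gap_half) * bas$v)
    d_caps <- pmin(sqrt(colSums((pts - e1)^2)), sqrt(colSums((pts - e2)^2))) - rt
    sdf <- pmin(sdf, ifelse(on_arc, d_torus, d_caps))
  }
  ax <- spec$vestibule_semiaxes_mm
  qv2 <- (pts - geom$vest_center) / ax
  d_vest <- (sqrt(colSums(qv2^2)) - 1) * min(ax)
  sdf <- pmin(sdf, d_vest)
  verts <- cochlea_curve(spec, geom)
  d_coch <- .dist_to_polyline(pts, verts) - spec$cochlea_tube_radius_mm
  pmin(sdf, d_coch)
}

# Smooth deterministic tissue texture, evaluated in anatomy (unposed)
# coordinates so it moves rigidly with the labyrinth. A fixed sum of
# incommensurate 3D sinusoids under a Gaussian envelope around the
# labyrinth: the petrous bone pattern surrounds the inner ear and fades
# with distance, so texture alignment and labyrinth alignment share one
# optimum (a periodic texture without the envelope admits false optima a
# wavelength away).
background_texture <- function(spec, pts) {
  amp <- spec$background_texture_amp
  if (amp <= 0) return(0)
  ctr <- (spec$grid_size - 1) / 2 * spec$spacing_mm
  k1 <- 2 * pi / 6.3 * c(0.8, 0.5, 0.33)
  k2 <- 2 * pi / 4.7 * c(-0.4, 0.9, 0.2)
  k3 <- 2 * pi / 8.9 * c(0.2, -0.3, 0.93)
  envelope <- exp(-colSums((pts - ctr)^2) / (2 * 8^2))
  amp * envelope * (0.5 * sin(colSums(pts * k1) + 1.3) +
                      0.3 * sin(colSums(pts * k2) + 2.1) +
                      0.2 * sin(colSums(pts * k3) + 0.7))
}

# Truth landmarks in unposed space: lateral extreme of the posterior canal
# torus, superior extreme of the superior canal torus, cochlear spiral apex.
unposed_landmarks <- function(spec, geom) {
  extreme <- function(ci, dir) {
    nn <- spec$canal_normals[, ci]
    u <- normalize3(dir - sum(dir * nn) * nn)
    geom$canal_centers[, ci] + spec$canal_torus_radii_mm[ci] * u
  }
  verts <- cochlea_curve(spec, geom)
  list(posterior_scc_lateral = extreme(1, c(1, 0, 0)),
       superior_scc_apex = extreme(2, c(0, 0, 1)),
       cochlea_apex = verts[, ncol(verts)])
}

# Error if any posed structure leaves the physical field of view.
check_phantom_bounds <- function(spec, geom) {
  lo <- rep(0, 3)
  hi <- (spec$grid_size - 1) * spec$spacing_mm
  inside <- function(pts, margin) {
    all(pts >= lo + margin - 1e-9) && all(pts <= hi - margin + 1e-9)
  }
  posed <- function(pts) transform_points(spec$pose, pts)
  th <- seq(0, 2 * pi, length.out = 73L)[-73L]
  for (ci in 1:3) {
    bas <- plane_basis(spec$canal_normals[, ci])
    circ <- geom$canal_centers[, ci] +
      spec$canal_torus_radii_mm[ci] * (outer(bas$u, cos(th)) + outer(bas$v, sin(th)))
    if (!inside(posed(circ), spec$canal_tube_radius_mm)) {
      stopf("posed %s canal exceeds the grid bounds",
            c("posterior", "superior", "lateral")[ci])
    }
  }
  vc <- posed(geom$vest_center)
  if (!inside(vc, max(spec$vestibule_semiaxes_mm))) {
    stopf("posed vestibule exceeds the grid bounds")
  }
  if (!inside(posed(cochlea_curve(spec, geom)), spec$cochlea_tube_radius_mm)) {
    stopf("posed cochlea exceeds the grid bounds")
  }
  invisible(TRUE)
}

#' Generate a synthetic labyrinth phantom
#'
#' Rasterizes the analytic labyrinth of a [phantom_spec()] by evaluating
#' its signed distance at every voxel center (with a half-voxel soft edge
#' to avoid aliasing), applies the rigid pose, adds the optional unposed
#' distractor, blurs, adds seeded noise, and mirrors the whole volume for
#' left chirality. Deterministic per seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `volume` (a [lab_volume()]), `truth`
#'   (list with `landmarks` ([landmark_triplet()]), `mask` (the labyrinth
#'   [lab_mask()]), `pose`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec)
  check_phantom_bounds(spec, geom)
  d <- spec$grid_size
  grid <- lab_volume(array(0, d), spacing = rep(spec$spacing_mm, 3))
  pts_fixed <- voxel_to_physical(grid, grid_index_matrix(d))
  # labyrinth posed by `pose`: evaluate the unposed geometry at pose^-1(x)
  pts_unposed <- transform_points(invert_transform(spec$pose), pts_fixed)
  sdf <- labyrinth_sdf(spec, geom, pts_unposed)
  occ <- pmin(pmax(0.5 - sdf / spec$spacing_mm, 0), 1)
  bg <- spec$background_intensity +
    background_texture(spec, pts_unposed)
  vox <- bg + (spec$fluid_intensity - bg) * occ
  if (!is.null(spec$distractor)) {
    dd <- sqrt(colSums((pts_fixed - spec$distractor$center_mm)^2)) -
      spec$distractor$radius_mm
    occ_d <- pmin(pmax(0.5 - dd / spec$spacing_mm, 0), 1)
    vox <- pmax(vox, spec$background_intensity +
                  (spec$distractor$intensity - spec$background_intensity) * occ_d)
  }
  vol <- lab_volume(array(vox, d), grid$spacing, grid$origin, grid$direction)
  if (spec$smoothing_sigma_mm > 0) vol <- smooth_volume(vol, spec$smoothing_sigma_mm)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, rnorm(prod(d), 0, spec$noise_sd))
    if (spec$noise_model == "rician") {
      im <- with_seed(substream_seed(spec$seed, "rician"),
                      rnorm(prod(d), 0, spec$noise_sd))
      vol$voxels <- array(sqrt((as.numeric(vol$voxels) + noise)^2 + im^2), d)
    } else {
      vol$voxels <- array(as.numeric(vol$voxels) + noise, d)
    }
  }
  mask <- lab_mask(array(sdf <= 0, d), grid$spacing, grid$origin,
                   grid$direction)
  lm0 <- unposed_landmarks(spec, geom)
  lm_pts <- transform_points(spec$pose,
                             cbind(lm0$posterior_scc_lateral,
                                   lm0$superior_scc_apex,
                                   lm0$cochlea_apex))
  if (identical(spec$chirality, "left")) {
    vol <- mirror_sagittal(vol)
    mask <- mirror_sagittal(mask)
    lm_pts <- mirror_point(vol, lm_pts)
  }
  landmarks <- landmark_triplet(lm_pts[, 1], lm_pts[, 2], lm_pts[, 3])
  structure(list(volume = vol,
                 truth = list(landmarks = landmarks, mask = mask,
                              pose = spec$pose),
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s-chirality, seed %d, %d labyrinth voxels\n",
              x$spec$chirality, x$spec$seed, sum(x$truth$mask$voxels)))
  print(x$volume)
  invisible(x)
}

#' Atlas phantom: the noise-free, identity-pose reference
#'
#' The fixed-image stand-in used throughout the test harness: the same
#' geometry as `base_spec` but with identity pose and no noise. A
#' distractor, if present in the base spec, stays at its canonical
#' position — as a real atlas would show the brainstem at its own location.
#'
#' @param base_spec A [phantom_spec()].
#' @return A `phantom` (see [generate_phantom()]).
#' @export
phantom_atlas <- function(base_spec = phantom_spec()) {
  spec <- base_spec
  spec$pose <- rigid_transform()
  spec$noise_sd <- 0
  spec$chirality <- "right"
  generate_phantom(spec)
}

#' Cohort jitter settings
#'
#' Per-subject variability of the phantom cohort. Pose offsets are drawn
#' uniformly in +/- the stated bounds; anatomy jitter is multiplicative
#' Gaussian on the canal radii and a random tilt of the canal planes.
#'
#' @param rotation_deg Pose rotation bound per axis (default 10 degrees).
#' @param translation_mm Pose translation bound per axis (default 4 mm).
#' @param canal_radius_frac SD of the multiplicative canal-radius jitter
#'   (default 0.06).
#' @param canal_tilt_deg SD of the canal-plane tilt (default 4 degrees).
#' @param distractor_shift_mm Bound of the distractor's own independent
#'   displacement per axis (default 3 mm; only used when the base spec has
#'   a distractor).
#' @return A list of class `cohort_variability`.
#' @export
cohort_variability <- function(rotation_deg = 10, translation_mm = 4,
                               canal_radius_frac = 0.06, canal_tilt_deg = 4,
                               distractor_shift_mm = 3) {
  structure(list(rotation_deg = rotation_deg, translation_mm = translation_mm,
                 canal_radius_frac = canal_radius_frac,
                 canal_tilt_deg = canal_tilt_deg,
                 distractor_shift_mm = distractor_shift_mm),
            class = "cohort_variability")
}

random_small_rotation <- function(bound_deg) {
  ang <- runif(3, -bound_deg, bound_deg) * pi / 180
  euler_rotation(ang[1], ang[2], ang[3])
}

#' Generate a phantom cohort
#'
#' `n` phantoms with independently jittered poses and anatomy, seeded
#' reproducibly: subject k is driven by a substream of `seed`, so cohorts
#' with the same seed are identical and cohorts with different seeds share
#' no noise realization. Jitters that push the geometry out of the grid are
#' resampled up to `max_retries` times.
#'
#' @param n Number of subjects (>= 1).
#' @param base_spec The common [phantom_spec()].
#' @param variability A [cohort_variability()]; use all-zero bounds for n
#'   identical-geometry phantoms differing only in noise.
#' @param seed Integer master seed.
#' @param max_retries Resampling attempts per subject (default 10).
#' @return A list of class `phantom_cohort`: `subjects` (list of
#'   `phantom`), `base_spec`, `seed`.
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(),
                            variability = cohort_variability(), seed = 1L) {
  stopifnot(n >= 1, inherits(base_spec, "phantom_spec"),
            inherits(variability, "cohort_variability"))
  max_retries <- 10L
  subjects <- vector("list", n)
  for (k in seq_len(n)) {
    sub_seed <- substream_seed(seed, sprintf("subject%03d", k))
    ok <- FALSE
    for (attempt in seq_len(max_retries)) {
      spec_k <- with_seed(substream_seed(sub_seed, sprintf("jitter%d", attempt)), {
        s <- base_spec
        ctr <- (s$grid_size - 1) / 2 * s$spacing_mm
        s$pose <- rigid_transform(
          random_small_rotation(variability$rotation_deg),
          runif(3, -variability$translation_mm, variability$translation_mm),
          center = ctr)
        s$canal_torus_radii_mm <- s$canal_torus_radii_mm *
          exp(rnorm(3, 0, variability$canal_radius_frac))
        if (variability$canal_tilt_deg > 0) {
          tilt <- random_small_rotation(variability$canal_tilt_deg)
          s$canal_normals <- apply(tilt %*% s$canal_normals, 2, normalize3)
        }
        if (!is.null(s$distractor) && variability$distractor_shift_mm > 0) {
          s$distractor$center_mm <- s$distractor$center_mm +
            runif(3, -variability$distractor_shift_mm,
                  variability$distractor_shift_mm)
        }
        s$seed <- substream_seed(sub_seed, "noise")
        s
      })
      ph <- tryCatch(generate_phantom(spec_k), error = function(e) e)
      if (!inherits(ph, "error")) {
        subjects[[k]] <- ph
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stopf("subject %d: jitter produced an invalid phantom %d times (last: %s)",
            k, max_retries, conditionMessage(ph))
    }
  }
  structure(list(subjects = subjects, base_spec = base_spec, seed = seed),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects, seed %d\n", length(x$subjects),
              x$seed))
  invisible(x)
}
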