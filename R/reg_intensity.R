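#' Atlas-derived "thick inner ear" (TIE) registration mask
#'
#' Binarizes the atlas at an intensity threshold (Otsu by default) and
#' volumetrically dilates the foreground with a Euclidean ball of the given
#' radius in voxels. The resulting mask restricts the registration metric to
#' the labyrinth and a safety margin around it, so that large bright
#' off-target structures cannot dominate the similarity metric.
#'
#' @param atlas A [lab_volume()] (the fixed atlas image).
#' @param intensity_threshold Numeric cutoff or `"otsu"`.
#' @param dilation_radius_voxels Ball radius in voxels (default 10; at the
#'   0.25 mm working resolution of the upsampled data this is 2.5 mm).
#' @return A [lab_mask()] on the atlas grid, a superset of the binarized
#'   foreground.
#' @export
make_tie_mask <- function(atlas, intensity_threshold = "otsu",
                          dilation_radius_voxels = 10) {
  stopifnot(is_lab_volume(atlas))
  m <- binarize(atlas, intensity_threshold)
  if (dilation_radius_voxels > 0) {
    m <- dilate_mask(m, dilation_radius_voxels)
  }
  m
}

#' Dilate a binary mask with a Euclidean ball
#'
#' Morphological dilation with the structuring element
#' `{(dx,dy,dz) : dx^2+dy^2+dz^2 <= r^2}` on the voxel lattice, computed by
#' FFT convolution with zero padding (equivalent to the brute-force lattice
#' dilation).
#'
#' @param mask A [lab_mask()].
#' @param radius_voxels Ball radius in voxels (>= 0; 0 returns the input).
#' @return The dilated [lab_mask()].
#' @export
dilate_mask <- function(mask, radius_voxels) {
  stopifnot(inherits(mask, "lab_mask"), radius_voxels >= 0)
  r <- as.integer(floor(radius_voxels + 1e-9))
  if (r == 0L || !any(mask$voxels)) return(mask)
  d <- dim(mask$voxels)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= radius_voxels^2 + 1e-9, ]
  s <- d + 2L * r
  A <- array(0, s)
  A[(r + 1):(r + d[1]), (r + 1):(r + d[2]), (r + 1):(r + d[3])] <-
    as.numeric(mask$voxels)
  K <- array(0, s)
  K[cbind(((off$dx + s[1]) %% s[1]) + 1L,
          ((off$dy + s[2]) %% s[2]) + 1L,
          ((off$dz + s[3]) %% s[3]) + 1L)] <- 1
  conv <- Re(fft(fft(A) * fft(K), inverse = TRUE)) / prod(s)
  out <- conv[(r + 1):(r + d[1]), (r + 1):(r + d[2]), (r + 1):(r + d[3])] > 0.5
  lab_mask(out, mask$spacing, mask$origin, mask$direction)
}

#' Geometric-center initialization
#'
#' The standard rigid initializer: identity rotation with the translation
#' that maps the moving domain's physical center onto the fixed domain's
#' physical center.
#'
#' @param moving,fixed [lab_volume()] objects.
#' @return A [rigid_transform()].
#' @export
geometric_center_init <- function(moving, fixed) {
  stopifnot(is_lab_volume(moving), is_lab_volume(fixed))
  rigid_transform(diag(3), volume_center(fixed) - volume_center(moving),
                  c(0, 0, 0))
}

#' Registration configuration
#'
#' One engine drives all three automatic methods; the presets differ only in
#' whether a fixed-image mask restricts the metric and in minor optimizer
#' constants:
#' * `"tie"` — mask-aided; requires `fixed_mask` (see [make_tie_mask()]).
#' * `"ants-like"`, `"elastix-like"` — unmasked baselines.
#'
#' The metric is Mattes-style mutual information (default 32 bins, 25%
#' random sampling of the metric region) over a 3-level multi-resolution
#' pyramid (shrink 4/2/1, Gaussian smoothing 2/1/0 mm), initialized by
#' [geometric_center_init()] and optimized by a derivative-free simplex
#' search per level. All sampling randomness derives from `random_seed`.
#'
#' @param preset `"tie"`, `"ants-like"` or `"elastix-like"`.
#' @param fixed_mask Optional [lab_mask()] on the fixed grid (required for
#'   `"tie"`).
#' @param histogram_bins Joint histogram bins per channel (>= 8).
#' @param sampling_fraction Fraction of metric-region voxels sampled, (0, 1].
#' @param pyramid List of `c(shrink, sigma_mm)` levels, coarse to fine;
#'   shrink factors >= 1 and non-increasing.
#' @param max_iterations Simplex iterations per pyramid level.
#' @param reltol Relative convergence tolerance of the simplex search.
#' @param init_search_deg Half-width (degrees) of the exhaustive rotation
#'   sweep at the coarsest level (0 disables the whole sweep).
#' @param init_search_mm Half-width (mm) of the matching translation sweep
#'   (0 keeps the sweep rotation-only).
#' @param init_search_steps Grid points per axis of those sweeps.
#' @param random_seed Integer seed for metric sampling.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(preset = c("tie", "ants-like", "elastix-like"),
                                fixed_mask = NULL,
                                histogram_bins = 32L,
                                sampling_fraction = 0.25,
                                pyramid = list(c(4, 2), c(2, 1), c(1, 0)),
                                max_iterations = NULL,
                                reltol = 1e-10,
                                init_search_deg = 15,
                                init_search_mm = 6,
                                init_search_steps = 7L,
                                random_seed = 1L) {
  preset <- match.arg(preset)
  if (identical(preset, "tie") && is.null(fixed_mask)) {
    stopf("the \"tie\" preset requires `fixed_mask` (see make_tie_mask())")
  }
  if (!is.null(fixed_mask)) {
    stopifnot(inherits(fixed_mask, "lab_mask"))
    if (!any(fixed_mask$voxels)) stopf("`fixed_mask` is empty")
  }
  if (histogram_bins < 8) stopf("`histogram_bins` must be >= 8")
  if (!(sampling_fraction > 0 && sampling_fraction <= 1)) {
    stopf("`sampling_fraction` must be in (0, 1]")
  }
  if (!length(pyramid)) stopf("`pyramid` must have at least one level")
  shrinks <- vapply(pyramid, `[`, 1, 1)
  if (any(shrinks < 1) || is.unsorted(rev(shrinks))) {
    stopf("pyramid shrink factors must be >= 1 and non-increasing")
  }
  # preset-specific optimizer constants; the engine is otherwise identical
  if (is.null(max_iterations)) {
    max_iterations <- switch(preset, "elastix-like" = 500L, 400L)
  }
  structure(list(preset = preset, metric = "mutual_information",
                 fixed_mask = fixed_mask,
                 histogram_bins = as.integer(histogram_bins),
                 sampling_fraction = sampling_fraction,
                 pyramid = pyramid,
                 max_iterations = as.integer(max_iterations),
                 reltol = reltol,
                 init_search_deg = init_search_deg,
                 init_search_mm = init_search_mm,
                 init_search_steps = as.integer(init_search_steps),
                 initializer = "geometric_center",
                 random_seed = as.integer(random_seed)),
            class = "registration_config")
}

# ---- multi-resolution helpers -------------------------------------------

# Separable Gaussian smoothing, sigma in mm (0 = no-op). Truncated at 3
# sigma with row-normalized weights.
smooth_volume <- function(volume, sigma_mm) {
  if (sigma_mm <= 0) return(volume)
  vox <- volume$voxels
  for (ax in 1:3) {
    sig <- sigma_mm / volume$spacing[ax]
    if (sig < 0.2) next
    n <- dim(vox)[ax]
    r <- max(1L, as.integer(ceiling(3 * sig)))
    k <- exp(-((-r:r)^2) / (2 * sig^2))
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      taps <- pmin(pmax(i + (-r:r), 1L), n)
      for (j in seq_along(taps)) W[i, taps[j]] <- W[i, taps[j]] + k[j]
    }
    W <- W / rowSums(W)
    vox <- apply_along_axis(vox, W, ax)
  }
  lab_volume(vox, volume$spacing, volume$origin, volume$direction)
}

# Downsample by an integer shrink factor using block means; trailing voxels
# that do not fill a block are dropped. New voxel centers are the block
# centroids, so the origin shifts by (f-1)/2 voxels.
shrink_volume <- function(volume, f) {
  f <- as.integer(f)
  if (f <= 1L) return(volume)
  vox <- volume$voxels
  d <- dim(vox)
  m <- pmax(d %/% f, 1L)
  for (ax in 1:3) {
    n <- dim(vox)[ax]
    mm <- m[ax]
    W <- matrix(0, mm, n)
    for (i in seq_len(mm)) W[i, ((i - 1) * f + 1):(i * f)] <- 1 / f
    vox <- apply_along_axis(vox, W, ax)
  }
  shift <- volume$direction %*% (volume$spacing * rep((f - 1) / 2, 3))
  lab_volume(vox, volume$spacing * f, volume$origin + as.numeric(shift),
             volume$direction)
}

shrink_mask <- function(mask, f) {
  v <- shrink_volume(lab_volume(array(as.numeric(mask$voxels), dim(mask$voxels)),
                                mask$spacing, mask$origin, mask$direction), f)
  lab_mask(v$voxels >= 0.5, v$spacing, v$origin, v$direction)
}

# ---- mutual information metric ------------------------------------------

mutual_information <- function(joint) {
  n <- sum(joint)
  if (n <= 0) return(0)
  p <- joint / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  outer_p <- outer(px, py)
  sum(p[nz] * log(p[nz] / outer_p[nz]))
}

#' Rigid intensity registration to a fixed atlas
#'
#' Finds the rigid transform maximizing the mutual information between the
#' fixed image and the transformed moving image, with metric samples drawn
#' only where the fixed mask is true (the whole grid when no mask is set).
#' Coarse-to-fine over the configured pyramid; deterministic for a given
#' `random_seed`. Optimizer failure is reported via `converged = FALSE`
#' with diagnostics, never as an error.
#'
#' @param moving,fixed [lab_volume()] objects.
#' @param config A [registration_config()].
#' @return A list of class `registration_result`: `transform` (a
#'   [rigid_transform()] mapping moving physical points into fixed space),
#'   `final_metric` (mutual information at the optimum, nats), `converged`,
#'   `iterations_per_level`, `notes`.
#' @export
register_rigid <- function(moving, fixed, config) {
  stopifnot(is_lab_volume(moving), is_lab_volume(fixed),
            inherits(config, "registration_config"))
  if (!is.null(config$fixed_mask) && !same_grid(config$fixed_mask, fixed)) {
    stopf("`fixed_mask` must live on the fixed image grid")
  }
  center <- volume_center(fixed)
  init <- geometric_center_init(moving, fixed)
  # candidate pool: the coarse sweeps may propose alternative starts that
  # are carried in parallel through the coarse levels; the mid level picks
  # the winner, so one misleading coarse basin cannot capture the search
  candidates <- list(c(0, 0, 0, init$translation))
  iters <- integer(0)
  notes <- character(0)
  final_metric <- NA_real_
  opt_ok <- TRUE
  p <- candidates[[1]]

  for (li in seq_along(config$pyramid)) {
    lvl <- config$pyramid[[li]]
    f <- lvl[1]; sigma <- lvl[2]
    fx <- shrink_volume(smooth_volume(fixed, sigma), f)
    mv <- shrink_volume(smooth_volume(moving, sigma), f)
    msk <- if (!is.null(config$fixed_mask)) {
      shrink_mask(config$fixed_mask, f)
    } else NULL

    cand <- if (is.null(msk)) {
      seq_len(prod(dim(fx$voxels)))
    } else {
      which(as.logical(msk$voxels))
    }
    if (!length(cand)) {
      return(registration_result(rigid_transform(euler_rotation(p[1], p[2], p[3]),
                                                 p[4:6], center),
                                 NA_real_, FALSE, iters,
                                 c(notes, "empty metric region at a pyramid level")))
    }
    n_samp <- max(1000L, min(length(cand),
                             as.integer(round(config$sampling_fraction * length(cand)))))
    n_samp <- min(n_samp, length(cand))
    sel <- with_seed(substream_seed(config$random_seed, paste0("level", li)), {
      if (n_samp < length(cand)) sort(sample(cand, n_samp)) else cand
    })
    idx0 <- arrayInd(sel, dim(fx$voxels)) - 1L
    pts_fixed <- voxel_to_physical(fx, t(idx0))
    fixed_vals <- as.numeric(fx$voxels)[sel]
    if (max(fixed_vals) == min(fixed_vals)) {
      return(registration_result(rigid_transform(euler_rotation(p[1], p[2], p[3]),
                                                 p[4:6], center),
                                 NA_real_, FALSE, iters,
                                 c(notes, "constant fixed image in metric region")))
    }
    mr <- range(mv$voxels)
    bins <- config$histogram_bins
    metric_fn <- local({
      fvals <- fixed_vals; pf <- pts_fixed; mvv <- mv
      fr <- range(fvals); fw <- (fr[2] - fr[1]) / (bins - 1)
      mw <- (mr[2] - mr[1]) / (bins - 1); if (mw <= 0) mw <- 1
      mov_arr <- as.numeric(mvv$voxels); mov_dim <- dim(mvv$voxels)
      n_total <- length(fvals)
      function(p) {
        R <- euler_rotation(p[1], p[2], p[3])
        pts <- crossprod(R, pf - center - p[4:6]) + center
        cont <- (crossprod(mvv$direction, pts - mvv$origin)) / mvv$spacing
        vals <- .trilinear_sample(mov_arr, mov_dim, cont, NA_real_)
        ok <- !is.na(vals)
        if (sum(ok) < max(10, 0.25 * n_total)) return(1)
        h <- .joint_hist_pv(fvals[ok], vals[ok], bins, fr[1], fw, mr[1], mw)
        -mutual_information(h)
      }
    })

    if (li == 1L && config$init_search_deg > 0) {
      # exhaustive sweeps at the coarsest level: MI against the labyrinth
      # has local optima in both rotation and translation that
      # multi-resolution alone does not remove. The sweep bests become
      # additional start candidates rather than replacing the center start.
      p0 <- candidates[[1]]
      rot_steps <- seq(-config$init_search_deg, config$init_search_deg,
                       length.out = config$init_search_steps) * pi / 180
      rot_grid <- as.matrix(expand.grid(rot_steps, rot_steps, rot_steps))
      vals <- apply(rot_grid, 1, function(a) metric_fn(c(a, p0[4:6])))
      p_rot <- c(rot_grid[which.min(vals), ], p0[4:6])
      candidates[[length(candidates) + 1L]] <- p_rot
      if (config$init_search_mm > 0) {
        tr_steps <- seq(-config$init_search_mm, config$init_search_mm,
                        length.out = config$init_search_steps)
        tr_grid <- as.matrix(expand.grid(tr_steps, tr_steps, tr_steps))
        vals_t <- apply(tr_grid, 1, function(tt) {
          metric_fn(c(p_rot[1:3], p_rot[4:6] + tt))
        })
        p_tr <- c(p_rot[1:3], p_rot[4:6] + tr_grid[which.min(vals_t), ])
        # refine the rotation once around the shifted position
        vals_r2 <- apply(rot_grid, 1, function(a) metric_fn(c(a, p_tr[4:6])))
        candidates[[length(candidates) + 1L]] <-
          c(rot_grid[which.min(vals_r2), ], p_tr[4:6])
      }
    }

    # Simplex search with restarts per candidate: a fresh simplex at the
    # incumbent escapes the premature collapse Nelder-Mead is prone to in
    # 6 dimensions. A level is converged when a restart no longer improves
    # the metric.
    scales <- list(c(0.05, 0.05, 0.05, 2, 2, 2),
                   c(0.01, 0.01, 0.01, 0.4, 0.4, 0.4))
    iters_lvl <- 0L
    plateau <- FALSE
    failed <- FALSE
    optimized <- vector("list", length(candidates))
    for (ci in seq_along(candidates)) {
      best <- list(par = candidates[[ci]],
                   value = metric_fn(candidates[[ci]]))
      iters_lvl <- iters_lvl + 1L
      for (r in seq_len(6L)) {
        ps <- scales[[min(r, length(scales))]]
        fit <- tryCatch(
          optim(best$par, metric_fn, method = "Nelder-Mead",
                control = list(maxit = config$max_iterations,
                               reltol = config$reltol, parscale = ps)),
          error = function(e) NULL)
        if (is.null(fit) || any(!is.finite(fit$par)) ||
            !is.finite(fit$value)) {
          failed <- TRUE
          break
        }
        iters_lvl <- iters_lvl + fit$counts[["function"]]
        improvement <- best$value - fit$value
        if (fit$value < best$value) best <- fit[c("par", "value")]
        if (improvement < 1e-5) {
          plateau <- TRUE
          break
        }
      }
      optimized[[ci]] <- best
    }
    if (failed) {
      opt_ok <- FALSE
      notes <- c(notes, sprintf("optimizer failure at level %d", li))
      break
    }
    ord <- order(vapply(optimized, `[[`, 1, "value"))
    if (li < length(config$pyramid) - 1L) {
      # keep the two best distinct candidates through the coarse levels
      keep <- ord[1]
      for (oi in ord[-1]) {
        if (length(keep) >= 2L) break
        if (max(abs(optimized[[oi]]$par - optimized[[keep[1]]]$par) /
                  c(1, 1, 1, 10, 10, 10)) > 0.01) {
          keep <- c(keep, oi)
        }
      }
      candidates <- lapply(optimized[keep], `[[`, "par")
    } else {
      candidates <- list(optimized[[ord[1]]]$par)
    }
    p <- candidates[[1]]
    iters <- c(iters, iters_lvl)
    if (li == length(config$pyramid)) {
      final_metric <- -optimized[[ord[1]]]$value
      if (!plateau) {
        opt_ok <- FALSE
        notes <- c(notes, "iteration cap reached at finest level")
      }
    }
  }

  transform <- rigid_transform(euler_rotation(p[1], p[2], p[3]), p[4:6], center)
  # sanity bounds: a "registration" that spun off is a non-convergence
  ang_deg <- rotation_angle(transform$rotation) * 180 / pi
  drift <- sqrt(sum((transform$translation - init$translation)^2))
  fov <- max(dim(fixed$voxels) * fixed$spacing)
  sane <- ang_deg <= 45 && drift <= fov / 2
  if (!sane) notes <- c(notes, sprintf("transform outside sanity bounds (%.1f deg, %.1f mm drift)", ang_deg, drift))
  registration_result(transform, final_metric, opt_ok && sane, iters, notes)
}

registration_result <- function(transform, final_metric, converged, iters,
                                notes) {
  structure(list(transform = transform, final_metric = final_metric,
                 converged = converged, iterations_per_level = iters,
                 notes = notes),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> converged: %s, MI %.4f nats\n",
              x$converged, x$final_metric))
  print(x$transform)
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
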