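#' Closed-form rigid fit from landmark correspondences (3P registration)
#'
#' Least-squares rigid transform mapping the moving landmarks onto the fixed
#' (atlas) landmarks: centroids are aligned, the rotation comes from the SVD
#' of the 3x3 cross-covariance with a determinant-sign correction so that no
#' reflection can be returned, and the translation follows. With exactly
#' three non-collinear points the solution is unique and tie-free. The
#' fiducial registration error (FRE, the RMS residual at the landmarks in
#' mm) is always computed; fits with FRE above `fre_warn_mm` are flagged
#' with a warning but still returned.
#'
#' @param moving,fixed [landmark_triplet()] objects (moving subject, fixed
#'   atlas).
#' @param fre_warn_mm Warn when the RMS fiducial residual exceeds this many
#'   mm (quality flag for suspect landmark sets; default 2 mm).
#' @return A list of class `landmark_fit`: `transform` (a
#'   [rigid_transform()] mapping moving physical points to fixed space),
#'   `fre_mm` (RMS residual), `residuals_mm` (per-landmark distances),
#'   `reflection_corrected` (logical).
#' @export
fit_rigid_from_landmarks <- function(moving, fixed, fre_warn_mm = 2) {
  stopifnot(inherits(moving, "landmark_triplet"),
            inherits(fixed, "landmark_triplet"))
  P <- landmark_matrix(moving)   # 3 x 3, columns are points
  Q <- landmark_matrix(fixed)
  cp <- rowMeans(P)
  cq <- rowMeans(Q)
  H <- (Q - cq) %*% t(P - cp)    # cross-covariance (fixed x moving)
  s <- svd(H)
  dsign <- sign(det(s$u %*% t(s$v)))
  # Three centered points are always coplanar, so the smallest singular
  # value is ~0 and a negative det(UV') there just reflects the arbitrary
  # sign of the third singular vector; only a materially positive third
  # singular value marks a genuinely reflective correspondence.
  corrected <- dsign < 0 && s$d[3] > 1e-9 * max(s$d[1], .Machine$double.eps)
  if (corrected) {
    warning("near-reflective landmark correspondence; determinant-sign correction applied",
            call. = FALSE)
  }
  S <- diag(c(1, 1, dsign))
  R <- s$u %*% S %*% t(s$v)
  tr <- as.numeric(cq - R %*% cp)
  transform <- rigid_transform(R, tr, c(0, 0, 0))
  res <- transform_points(transform, P) - Q
  dists <- sqrt(colSums(res^2))
  fre <- sqrt(mean(dists^2))
  if (is.finite(fre_warn_mm) && fre > fre_warn_mm) {
    warning(sprintf("fiducial registration error %.2f mm exceeds %.2f mm; check landmark placement",
                    fre, fre_warn_mm), call. = FALSE)
  }
  structure(list(transform = transform, fre_mm = fre,
                 residuals_mm = setNames(dists, LANDMARK_NAMES),
                 reflection_corrected = corrected),
            class = "landmark_fit")
}

#' @export
print.landmark_fit <- function(x, ...) {
  cat(sprintf("<landmark_fit> FRE %.4g mm%s\n", x$fre_mm,
              if (x$reflection_corrected) " (reflection-corrected)" else ""))
  print(x$transform)
  invisible(x)
}

#' Resample a volume through a rigid transform onto a reference grid
#'
#' Produces a volume on the reference (atlas) grid whose value at each voxel
#' is the trilinear interpolation of the moving volume at the
#' inverse-mapped physical point. Points falling outside the moving domain
#' get `background`. This is the "hardening" step that turns a fitted
#' transform into a registered image.
#'
#' @param moving A [lab_volume()] to resample.
#' @param transform A [rigid_transform()] mapping moving physical points
#'   into fixed (reference) physical space.
#' @param reference A [lab_volume()] or [lab_mask()] defining the output
#'   grid.
#' @param background Fill value outside the moving domain (default 0).
#' @return A [lab_volume()] on the reference grid.
#' @export
resample_linear <- function(moving, transform, reference, background = 0) {
  stopifnot(is_lab_volume(moving), is_rigid_transform(transform),
            is_lab_volume(reference))
  d <- dim(reference$voxels)
  idx <- grid_index_matrix(d)
  pts_fixed <- voxel_to_physical(reference, idx)
  pts_moving <- transform_points(invert_transform(transform), pts_fixed)
  cont <- physical_to_voxel(moving, pts_moving)
  vals <- .trilinear_sample(as.numeric(moving$voxels), dim(moving$voxels),
                            cont, background)
  lab_volume(array(vals, d), reference$spacing, reference$origin,
             reference$direction)
}

# 3 x prod(d) matrix of all 0-based voxel indices, fastest along axis 1
# (matching R array linearization).
grid_index_matrix <- function(d) {
  rbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
        rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

#' Sample a volume at arbitrary physical points
#'
#' Trilinear interpolation of a volume at physical-space points, with a
#' background value outside the grid.
#'
#' @param volume A [lab_volume()].
#' @param points 3 x n matrix (or 3-vector) of physical points in mm.
#' @param background Value returned outside the grid.
#' @return Numeric vector of length n.
#' @export
sample_volume <- function(volume, points, background = 0) {
  stopifnot(is_lab_volume(volume))
  cont <- physical_to_voxel(volume, as_points3(points))
  .trilinear_sample(as.numeric(volume$voxels), dim(volume$voxels), cont,
                    background)
}
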