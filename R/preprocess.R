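#' Crop a rectangular ROI from a volume
#'
#' Extracts the sub-grid `[lower, upper)` (0-based voxel indices, upper
#' exclusive). The origin is shifted so every retained voxel keeps its
#' physical position; spacing and direction are unchanged.
#'
#' @param volume A [lab_volume()].
#' @param lower,upper Integer length-3 corner indices, `lower < upper`
#'   per axis, within the grid.
#' @return The cropped [lab_volume()].
#' @export
crop_roi <- function(volume, lower, upper) {
  stopifnot(is_lab_volume(volume))
  lower <- as.integer(lower); upper <- as.integer(upper)
  d <- dim(volume$voxels)
  if (length(lower) != 3L || length(upper) != 3L) {
    stopf("`lower` and `upper` must each have 3 components")
  }
  if (any(lower < 0L) || any(upper > d) || any(lower >= upper)) {
    stopf("crop box [%s, %s) out of bounds for grid %s",
          paste(lower, collapse = ","), paste(upper, collapse = ","),
          paste(d, collapse = "x"))
  }
  vox <- volume$voxels[(lower[1] + 1):upper[1],
                       (lower[2] + 1):upper[2],
                       (lower[3] + 1):upper[3], drop = FALSE]
  origin <- as.numeric(voxel_to_physical(volume, lower))
  out <- lab_volume(vox, volume$spacing, origin, volume$direction)
  if (inherits(volume, "lab_mask")) {
    out <- lab_mask(out$voxels, out$spacing, out$origin, out$direction)
  }
  out
}

# Catmull-Rom (a = -0.5) cubic kernel weights for fractional offset t in
# [0, 1) over the four taps floor-1 .. floor+2.
catmull_rom_weights <- function(t) {
  c(-0.5 * t^3 + t^2 - 0.5 * t,
    1.5 * t^3 - 2.5 * t^2 + 1,
    -1.5 * t^3 + 2 * t^2 + 0.5 * t,
    0.5 * t^3 - 0.5 * t^2)
}

# (2n x n) interpolation matrix for one axis of the 2x upsampling: output
# center m sits at input coordinate m/2 - 1/4; boundary taps are clamped
# (replicate padding).
upsample_axis_matrix <- function(n) {
  W <- matrix(0, 2L * n, n)
  for (m in seq_len(2L * n) - 1L) {
    u <- m / 2 - 0.25
    i0 <- floor(u)
    w <- catmull_rom_weights(u - i0)
    taps <- pmin(pmax(i0 + (-1L:2L), 0L), n - 1L)
    for (k in 1:4) W[m + 1L, taps[k] + 1L] <- W[m + 1L, taps[k] + 1L] + w[k]
  }
  W
}

# Apply a per-axis linear operator W (m_out x m_in) along the given axis of
# a 3D array.
apply_along_axis <- function(vox, W, axis) {
  d <- dim(vox)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  x <- aperm(vox, perm)
  dp <- dim(x)
  y <- W %*% matrix(x, nrow = dp[1])
  y <- array(y, c(nrow(W), dp[2], dp[3]))
  aperm(y, order(perm))
}

#' Two-fold cubic upsampling
#'
#' Doubles every axis (n voxels become 2n) with separable tricubic
#' Catmull-Rom interpolation, halving the spacing. New voxel centers sit at
#' quarter-spacing offsets around the old centers so the physical field of
#' view is preserved; boundary taps use replicate padding.
#'
#' @param volume A [lab_volume()] with at least 4 voxels per axis.
#' @return The upsampled [lab_volume()].
#' @export
upsample_2x <- function(volume) {
  stopifnot(is_lab_volume(volume))
  d <- dim(volume$voxels)
  if (any(d < 4L)) {
    stopf("upsampling needs >= 4 voxels per axis (cubic kernel support); got %s",
          paste(d, collapse = "x"))
  }
  vox <- volume$voxels
  for (ax in 1:3) vox <- apply_along_axis(vox, upsample_axis_matrix(d[ax]), ax)
  # first output center sits a quarter of the old spacing before the first
  # input center, along each voxel axis
  shift <- volume$direction %*% (volume$spacing * rep(-0.25, 3))
  lab_volume(vox, volume$spacing / 2, volume$origin + as.numeric(shift),
             volume$direction)
}

#' Mirror a volume across the sagittal plane
#'
#' Flips the volume across the plane through the grid center perpendicular
#' to the left-right physical axis (the first axis of the package's
#' coordinate convention), turning a left inner ear into right-ear
#' orientation. The reversal is an index flip on the voxel axis most aligned
#' with physical left-right; geometry is unchanged, so the output remains a
#' legal right-handed volume and the operation is an exact involution.
#'
#' @param volume A [lab_volume()] or [lab_mask()].
#' @return The mirrored volume on the same grid.
#' @export
mirror_sagittal <- function(volume) {
  stopifnot(is_lab_volume(volume))
  ax <- which.max(abs(volume$direction[1, ]))
  d <- dim(volume$voxels)
  idx <- rev(seq_len(d[ax]))
  vox <- switch(ax,
                volume$voxels[idx, , , drop = FALSE],
                volume$voxels[, idx, , drop = FALSE],
                volume$voxels[, , idx, drop = FALSE])
  out <- lab_volume(vox, volume$spacing, volume$origin, volume$direction)
  if (inherits(volume, "lab_mask")) {
    out <- lab_mask(out$voxels, out$spacing, out$origin, out$direction)
  }
  out
}

#' Mirror a physical point the same way [mirror_sagittal()] mirrors voxels
#'
#' Reflects a physical point across the same grid-centered sagittal plane,
#' so that landmark coordinates can follow a mirrored volume.
#'
#' @param volume The [lab_volume()] defining the grid.
#' @param point 3-vector or 3 x n matrix of physical points (mm).
#' @return Mirrored points, same shape convention as [transform_points()].
#' @export
mirror_point <- function(volume, point) {
  stopifnot(is_lab_volume(volume))
  pts <- as_points3(point)
  ax <- which.max(abs(volume$direction[1, ]))
  idx <- physical_to_voxel(volume, pts)
  idx[ax, ] <- (dim(volume$voxels)[ax] - 1) - idx[ax, ]
  voxel_to_physical(volume, idx)
}
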