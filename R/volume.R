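#' 3D scalar volume with physical geometry
#'
#' The universal image currency of the package: a rectangular 3D grid of
#' scalar intensities together with its physical geometry. Voxel index
#' `(i, j, k)` (0-based) maps to the physical point
#' `origin + direction %*% (spacing * c(i, j, k))` in mm; indices address
#' voxel centers, and physical space is a right-handed RAS-like frame
#' (first axis = left-right, second = posterior-anterior, third =
#' inferior-superior).
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing Numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin Numeric length-3, physical position (mm) of the center of
#'   voxel `(0, 0, 0)`.
#' @param direction 3x3 orthonormal matrix whose columns are the physical
#'   directions of the voxel axes.
#'
#' @return An object of class `lab_volume`.
#' @export
lab_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stopf("`voxels` must be a 3D array (got %d dimension(s))",
          length(dim(voxels) %||% dim(as.array(voxels))))
  }
  if (any(dim(voxels) < 1L)) stopf("voxel grid must be non-empty")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("`spacing` must be 3 positive finite numbers")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stopf("`origin` must be 3 finite numbers")
  }
  check_orthonormal(direction)
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         direction = direction),
    class = "lab_volume"
  )
}

check_orthonormal <- function(direction, tol = 1e-9) {
  if (!is.matrix(direction) || any(dim(direction) != c(3L, 3L))) {
    stopf("`direction` must be a 3x3 matrix")
  }
  if (max(abs(crossprod(direction) - diag(3))) > sqrt(tol)) {
    stopf("`direction` must be orthonormal (t(D) %%*%% D = I)")
  }
  invisible(direction)
}

#' @export
print.lab_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<lab_volume> %d x %d x %d voxels, spacing (%s) mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = ", ")))
  cat(sprintf("  origin (%s) mm, intensity range [%.4g, %.4g]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.lab_volume <- function(x) dim(x$voxels)

is_lab_volume <- function(x) inherits(x, "lab_volume")

#' Map voxel indices to physical coordinates
#'
#' @param volume A [lab_volume()].
#' @param index Numeric 3-vector or 3 x n matrix of (possibly fractional)
#'   0-based voxel indices.
#' @return 3 x n matrix of physical points in mm.
#' @export
voxel_to_physical <- function(volume, index) {
  idx <- as_points3(index)
  volume$direction %*% (volume$spacing * idx) + volume$origin
}

#' Map physical coordinates to continuous voxel indices
#'
#' @inheritParams voxel_to_physical
#' @param point Numeric 3-vector or 3 x n matrix of physical points in mm.
#' @return 3 x n matrix of continuous 0-based voxel indices.
#' @export
physical_to_voxel <- function(volume, point) {
  pts <- as_points3(point)
  (crossprod(volume$direction, pts - volume$origin)) / volume$spacing
}

as_points3 <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != 3L) stopf("points must be a 3 x n matrix")
    return(x)
  }
  if (length(x) != 3L) stopf("a point must have 3 components")
  matrix(as.numeric(x), nrow = 3L)
}

#' Physical center of a volume's field of view
#'
#' The geometric center of the image domain: the physical point midway
#' between the centers of the first and last voxels.
#'
#' @inheritParams voxel_to_physical
#' @return Numeric length-3 point in mm.
#' @export
volume_center <- function(volume) {
  d <- dim(volume$voxels)
  as.numeric(voxel_to_physical(volume, (d - 1) / 2))
}

#' Check that two volumes live on the identical grid
#'
#' @param a,b [lab_volume()] or [lab_mask()] objects.
#' @param tol Geometric tolerance in mm.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$voxels) == dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' Binary mask on a volume grid
#'
#' A logical 3D array sharing the geometry fields of [lab_volume()]. Masks
#' used as registration or colocalization ROIs must contain at least one
#' `TRUE` voxel.
#'
#' @param voxels 3D logical (or 0/1 numeric) array.
#' @inheritParams lab_volume
#' @return An object of class `lab_mask` (also a `lab_volume` structurally).
#' @export
lab_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     direction = diag(3)) {
  v <- lab_volume(array(as.logical(voxels), dim(voxels)), spacing, origin,
                  direction)
  class(v) <- c("lab_mask", class(v))
  v
}

#' @export
print.lab_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<lab_mask> %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' Convert a volume to a mask by thresholding
#'
#' @param volume A [lab_volume()].
#' @param threshold Either a numeric cutoff (voxels strictly greater are
#'   foreground) or `"otsu"` for Otsu's between-class-variance threshold.
#' @return A [lab_mask()] on the same grid.
#' @export
binarize <- function(volume, threshold = "otsu") {
  stopifnot(is_lab_volume(volume))
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(as.numeric(volume$voxels))
  } else {
    stopifnot(is_scalar_number(threshold))
    threshold
  }
  fg <- volume$voxels > thr
  if (!any(fg)) stopf("thresholding at %.6g leaves an empty foreground", thr)
  lab_mask(fg, volume$spacing, volume$origin, volume$direction)
}

# Otsu's method on a 256-bin histogram of the intensity range.
otsu_threshold <- function(x, bins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) stopf("cannot threshold a constant image")
  edges <- seq(r[1], r[2], length.out = bins + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins = bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}
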