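#' Rigid transform in physical space
#'
#' A rotation plus translation (with an optional fixed rotation center)
#' mapping moving-space physical points into fixed (atlas)-space physical
#' points:
#' `y = R %*% (x - center) + center + translation`.
#' Rigidity is enforced at construction: `R` must be a proper rotation
#' (orthonormal, determinant +1), so the transform preserves all distances
#' and angles — no scaling, shearing, or reflection.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Numeric length-3, mm.
#' @param center Numeric length-3 rotation center, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  center <- as.numeric(center)
  check_rotation(rotation)
  if (length(translation) != 3L || any(!is.finite(translation))) {
    stopf("`translation` must be 3 finite numbers")
  }
  if (length(center) != 3L || any(!is.finite(center))) {
    stopf("`center` must be 3 finite numbers")
  }
  structure(list(rotation = rotation, translation = translation,
                 center = center),
            class = "rigid_transform")
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L))) {
    stopf("`rotation` must be a 3x3 matrix")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stopf("`rotation` is not orthonormal")
  }
  if (det(R) < 0) {
    stopf("`rotation` has negative determinant (reflection); rigid transforms forbid reflections")
  }
  invisible(R)
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%s) mm\n",
              ang, paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Apply a rigid transform to physical points
#'
#' @param transform A [rigid_transform()].
#' @param point 3-vector or 3 x n matrix of physical points (mm).
#' @return 3 x n matrix of transformed points.
#' @export
transform_points <- function(transform, point) {
  stopifnot(is_rigid_transform(transform))
  pts <- as_points3(point)
  transform$rotation %*% (pts - transform$center) + transform$center +
    transform$translation
}

#' Compose two rigid transforms
#'
#' Returns the rigid transform equivalent to applying `inner` first, then
#' `outer`. Closure under composition is re-verified on the result.
#'
#' @param outer,inner [rigid_transform()] objects.
#' @return A [rigid_transform()] with center at the origin.
#' @export
compose_transforms <- function(outer, inner) {
  stopifnot(is_rigid_transform(outer), is_rigid_transform(inner))
  # Reduce both to y = R x + t form, then chain.
  Ri <- inner$rotation
  ti <- inner$translation + inner$center - Ri %*% inner$center
  Ro <- outer$rotation
  to <- outer$translation + outer$center - Ro %*% outer$center
  R <- Ro %*% Ri
  # re-orthonormalize to stop rounding drift across long chains
  R <- project_to_rotation(R)
  rigid_transform(R, as.numeric(Ro %*% ti + to), c(0, 0, 0))
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse [rigid_transform()] (center at the origin).
#' @export
invert_transform <- function(transform) {
  stopifnot(is_rigid_transform(transform))
  R <- transform$rotation
  t <- transform$translation + transform$center - R %*% transform$center
  rigid_transform(t(R), as.numeric(-crossprod(R, t)), c(0, 0, 0))
}

# Nearest proper rotation in Frobenius norm (polar decomposition via SVD).
project_to_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

#' Rotation angle of a rotation matrix
#'
#' The magnitude of the axis-angle representation, in radians.
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  # atan2 form: well-conditioned near 0 and pi, unlike acos of the trace
  s <- sqrt((R[3, 2] - R[2, 3])^2 + (R[1, 3] - R[3, 1])^2 +
              (R[2, 1] - R[1, 2])^2) / 2
  c_ <- (sum(diag(R)) - 1) / 2
  atan2(s, c_)
}

#' Euler-angle rotation matrix
#'
#' Rotation about the fixed x, y, z axes applied in that order:
#' `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)`.
#'
#' @param rx,ry,rz Angles in radians.
#' @return 3x3 rotation matrix.
#' @export
euler_rotation <- function(rx = 0, ry = 0, rz = 0) {
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Write a rigid transform to a text file
#'
#' Plain-text serialization: a comment header documenting the layout, then
#' 12 numbers — the row-major rotation matrix, the translation, and the
#' rotation center.
#'
#' @param transform A [rigid_transform()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  stopifnot(is_rigid_transform(transform))
  lines <- c(
    "# rigid transform: y = R (x - center) + center + translation",
    "# rows 1-3: rotation matrix (row-major); row 4: translation mm; row 5: center mm",
    apply(transform$rotation, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
    paste(sprintf("%.17g", transform$translation), collapse = " "),
    paste(sprintf("%.17g", transform$center), collapse = " ")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a rigid transform written by [write_transform()]
#'
#' @param path File path.
#' @return A [rigid_transform()].
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stopf("transform file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 5L) {
    stopf("expected 5 numeric rows (3 rotation, translation, center), got %d",
          length(lines))
  }
  nums <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(vapply(nums, length, 1L) != 3L)) {
    stopf("each row of a transform file must hold 3 numbers")
  }
  R <- do.call(rbind, nums[1:3])
  rigid_transform(R, nums[[4]], nums[[5]])
}
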