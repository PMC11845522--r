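#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 image (.nii or .nii.gz) into a [lab_volume()], taking
#' spacing, origin and direction from the header affine (sform preferred,
#' qform fallback). Intensities are passed through unmodified.
#'
#' @param path Path to a NIfTI file with exactly 3 spatial dimensions.
#' @return A [lab_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stopf("expected a 3D image, got %dD (%s)", length(d),
          paste(d, collapse = " x "))
  }
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  A <- unclass(aff)[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(A^2))
  if (any(spacing <= 0)) stopf("NIfTI header has non-positive voxel spacing")
  direction <- sweep(A, 2, spacing, "/")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-3) {
    stopf("NIfTI direction matrix is not orthonormal; oblique/sheared grids are not supported")
  }
  direction <- project_direction(direction)
  lab_volume(array(as.numeric(img), d), spacing = spacing,
             origin = unclass(aff)[1:3, 4], direction = direction)
}

# Snap a nearly-orthonormal direction matrix (float32 header storage) to the
# closest exactly orthonormal one.
project_direction <- function(D) {
  s <- svd(D)
  s$u %*% t(s$v)
}

#' Write a volume to NIfTI
#'
#' Writes voxels at double precision with the full affine stored in both
#' sform and qform, so geometry reproduces on re-read to header (float32)
#' precision.
#'
#' @param volume A [lab_volume()] or [lab_mask()] (masks are written as 0/1).
#' @param path Output path (.nii or .nii.gz); the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_lab_volume(volume))
  if (!dir.exists(dirname(path))) {
    stopf("directory does not exist: %s", dirname(path))
  }
  vox <- volume$voxels
  if (is.logical(vox)) vox <- array(as.numeric(vox), dim(vox))
  img <- RNifti::asNifti(vox, datatype = "double")
  aff <- rbind(cbind(volume$direction %*% diag(volume$spacing), volume$origin),
               c(0, 0, 0, 1))
  dimnames(aff) <- NULL
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path Path to a NIfTI file; voxels > 0.5 become foreground.
#' @return A [lab_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  lab_mask(v$voxels > 0.5, v$spacing, v$origin, v$direction)
}
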