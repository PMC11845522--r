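# The three anatomical fiducials of the semi-manual registration:
# the most lateral point of the posterior semicircular canal, the most
# superior point of the superior semicircular canal, and the cochlear apex.
LANDMARK_NAMES <- c("posterior_scc_lateral", "superior_scc_apex", "cochlea_apex")

#' Landmark triplet
#'
#' The three named anatomical fiducials used by the three-point (3P)
#' registration, as physical-space points in mm.
#'
#' @param posterior_scc_lateral,superior_scc_apex,cochlea_apex Numeric
#'   length-3 physical points (mm).
#' @return An object of class `landmark_triplet`.
#' @export
landmark_triplet <- function(posterior_scc_lateral, superior_scc_apex,
                             cochlea_apex) {
  pts <- rbind(as.numeric(posterior_scc_lateral),
               as.numeric(superior_scc_apex),
               as.numeric(cochlea_apex))
  if (ncol(pts) != 3L || any(!is.finite(pts))) {
    stopf("each landmark must be 3 finite coordinates (mm)")
  }
  check_noncollinear(pts)
  structure(list(points = pts, names = LANDMARK_NAMES),
            class = "landmark_triplet")
}

# A rigid fit from three points is underdetermined when they are (nearly)
# collinear: the rotation about the common line is free.
check_noncollinear <- function(pts, tol = 1e-6) {
  if (min(dist(pts)) < tol) {
    stopf("landmarks must be pairwise distinct")
  }
  a <- pts[2, ] - pts[1, ]
  b <- pts[3, ] - pts[1, ]
  area <- sqrt(sum(cross3(a, b)^2)) / 2
  if (area <= tol) {
    stopf("landmarks are collinear (triangle area %.3g mm^2); the rigid fit is underdetermined",
          area)
  }
  invisible(pts)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.landmark_triplet <- function(x, ...) {
  cat("<landmark_triplet> (mm)\n")
  for (i in 1:3) {
    cat(sprintf("  %-22s %s\n", x$names[i],
                paste(signif(x$points[i, ], 6), collapse = ", ")))
  }
  invisible(x)
}

#' Landmark points as a matrix
#'
#' @param triplet A [landmark_triplet()].
#' @return 3 x 3 matrix, one landmark per column, rows x/y/z (mm).
#' @export
landmark_matrix <- function(triplet) {
  stopifnot(inherits(triplet, "landmark_triplet"))
  t(triplet$points)
}

#' Read a landmark triplet from CSV
#'
#' Expects a delimited text file with header `name,x_mm,y_mm,z_mm` and
#' exactly the three canonical rows (`posterior_scc_lateral`,
#' `superior_scc_apex`, `cochlea_apex`), matched case-insensitively, in any
#' order.
#'
#' @param path File path.
#' @return A [landmark_triplet()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stopf("landmark file must have columns %s", paste(need, collapse = ", "))
  }
  nm <- tolower(trimws(df$name))
  if (anyDuplicated(nm)) {
    stopf("duplicate landmark name(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  missing <- setdiff(LANDMARK_NAMES, nm)
  if (length(missing)) {
    stopf("missing landmark(s): %s", paste(missing, collapse = ", "))
  }
  row_of <- function(name) {
    as.numeric(df[match(name, nm), c("x_mm", "y_mm", "z_mm")])
  }
  landmark_triplet(row_of("posterior_scc_lateral"),
                   row_of("superior_scc_apex"),
                   row_of("cochlea_apex"))
}

#' Write a landmark triplet to CSV
#'
#' @param triplet A [landmark_triplet()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(triplet, path) {
  stopifnot(inherits(triplet, "landmark_triplet"))
  df <- data.frame(name = triplet$names,
                   x_mm = triplet$points[, 1],
                   y_mm = triplet$points[, 2],
                   z_mm = triplet$points[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply a rigid transform to a landmark triplet
#'
#' @param triplet A [landmark_triplet()].
#' @param transform A [rigid_transform()].
#' @return The transformed [landmark_triplet()].
#' @export
transform_landmarks <- function(triplet, transform) {
  pts <- transform_points(transform, landmark_matrix(triplet))
  landmark_triplet(pts[, 1], pts[, 2], pts[, 3])
}
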