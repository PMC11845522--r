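test_that("NIfTI write/read round trip preserves voxels and geometry", {
  dir <- withr::local_tempdir()
  th <- 0.25
  vol <- rand_volume(c(8L, 8L, 8L), seed = 42, spacing = c(0.5, 0.5, 1.0),
                     origin = c(1.5, -2, 3),
                     direction = euler_rotation(rz = th))
  p <- file.path(dir, "vol.nii.gz")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_identical(back$voxels, vol$voxels)
  expect_lt(max(abs(back$spacing - vol$spacing)), 1e-6)
  expect_lt(max(abs(back$origin - vol$origin)), 1e-6)
  expect_lt(max(abs(back$direction - vol$direction)), 1e-6)

  # integer data: voxel sum exact
  ivol <- lab_volume(array(sample.int(1000, 64, replace = TRUE), c(4, 4, 4)))
  p2 <- file.path(dir, "int.nii")
  write_volume(ivol, p2)
  expect_equal(sum(read_volume(p2)$voxels), sum(ivol$voxels))
})

test_that("volumes carry the acquisition geometry they were given", {
  vol <- lab_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
  expect_equal(vol$spacing, c(0.5, 0.5, 0.5))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "iso.nii.gz")
  write_volume(vol, p)
  expect_equal(read_volume(p)$spacing, c(0.5, 0.5, 0.5), tolerance = 1e-9)
})

test_that("read_volume rejects non-3D images with a dimension diagnostic", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "vol4d.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), p)
  expect_error(read_volume(p), "4D")
  expect_error(read_volume(file.path(dir, "nope.nii")), "not found")
})

test_that("volume invariants are enforced at construction", {
  expect_error(lab_volume(matrix(0, 3, 3)), "3D")
  expect_error(lab_volume(array(0, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "spacing")
  skewed <- diag(3); skewed[1, 2] <- 0.3
  expect_error(lab_volume(array(0, c(2, 2, 2)), direction = skewed),
               "orthonormal")
})

test_that("rigid transform algebra closes over the type", {
  for (s in 1:5) {
    a <- rand_rigid(s, center = c(1, 2, 3))
    b <- rand_rigid(s + 100)
    ab <- compose_transforms(a, b)
    expect_lt(max(abs(crossprod(ab$rotation) - diag(3))), 1e-9)
    expect_equal(det(ab$rotation), 1, tolerance = 1e-9)
    # composition acts like sequential application
    set.seed(s)
    x <- matrix(runif(9, -5, 5), 3)
    expect_equal(transform_points(ab, x),
                 transform_points(a, transform_points(b, x)),
                 tolerance = 1e-9)
    # inverse undoes
    inv <- invert_transform(a)
    expect_equal(transform_points(inv, transform_points(a, x)), x,
                 tolerance = 1e-9)
  }
})

test_that("transform text serialization round trips", {
  dir <- withr::local_tempdir()
  tr <- rand_rigid(9, center = c(4, -1, 2))
  p <- file.path(dir, "t.tfm")
  write_transform(tr, p)
  back <- read_transform(p)
  expect_equal(back$rotation, tr$rotation, tolerance = 1e-12)
  expect_equal(back$translation, tr$translation, tolerance = 1e-12)
  expect_equal(back$center, tr$center, tolerance = 1e-12)
})

test_that("rigid constructor rejects reflections and non-rotations", {
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "reflection")
  expect_error(rigid_transform(diag(3) * 2), "orthonormal")
})

test_that("landmark CSV parsing honours names, order and validity", {
  dir <- withr::local_tempdir()
  tri <- landmark_triplet(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  p <- file.path(dir, "lm.csv")
  write_landmarks(tri, p)
  expect_equal(landmark_matrix(read_landmarks(p)), landmark_matrix(tri),
               tolerance = 1e-12)

  # order and case insensitivity
  writeLines(c("name,x_mm,y_mm,z_mm",
               "COCHLEA_APEX,0,10,0",
               "posterior_scc_lateral,0,0,0",
               "Superior_SCC_Apex,10,0,0"), p)
  expect_equal(landmark_matrix(read_landmarks(p)), landmark_matrix(tri),
               tolerance = 1e-12)

  writeLines(c("name,x_mm,y_mm,z_mm",
               "posterior_scc_lateral,0,0,0",
               "superior_scc_apex,10,0,0"), p)
  expect_error(read_landmarks(p), "cochlea_apex")

  writeLines(c("name,x_mm,y_mm,z_mm",
               "posterior_scc_lateral,0,0,0",
               "superior_scc_apex,1,0,0",
               "cochlea_apex,2,0,0"), p)
  expect_error(read_landmarks(p), "collinear")
})

test_that("rating tables are validated on the half-step Likert scale", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "r.csv")
  writeLines(c("dataset_id,method,rater_id,grade", "d001,TIE,EK,2.5"), p)
  r <- read_ratings(p)
  expect_equal(r$grade, 2.5)
  expect_equal(r$method, "TIE")

  writeLines(c("dataset_id,method,rater_id,grade", "d001,TIE,EK,6.5"), p)
  expect_error(read_ratings(p), "outside")
  writeLines(c("dataset_id,method,rater_id,grade", "d001,TIE,EK,2.25"), p)
  expect_error(read_ratings(p), "half-step")
  writeLines(c("dataset_id,method,rater_id,grade", "d001,FSL,EK,2"), p)
  expect_error(read_ratings(p), "unknown method")
  writeLines(c("dataset_id,method,rater_id,grade",
               "d001,TIE,EK,2", "d001,TIE,EK,3"), p)
  expect_error(read_ratings(p), "duplicate")
})
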