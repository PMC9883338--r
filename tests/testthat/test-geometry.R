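# Coordinate conventions and affine decomposition.

test_that("ras_to_lps negates the first two axes and is an involution", {
  expect_equal(ras_to_lps(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(ras_to_lps(c(1, 2, 3)), c(-1, -2, 3))
  set.seed(4)
  for (i in 1:20) {
    p <- stats::runif(3, -100, 100)
    q <- stats::runif(3, -100, 100)
    expect_equal(ras_to_lps(ras_to_lps(p)), p)
    # distances preserved
    expect_equal(sqrt(sum((ras_to_lps(p) - ras_to_lps(q))^2)),
                 sqrt(sum((p - q)^2)))
  }
  expect_error(ras_to_lps(c(1, NaN, 3)), class = "dicomnav_input_error")
})

# brute-force oracle: compare the slice-geometry reconstruction of every
# voxel centre with the direct affine path
expect_voxel_centre_agreement <- function(affine, shape, tol = 1e-3) {
  g <- affine_to_slice_geometry(affine, shape)
  worst <- 0
  for (i in seq_len(shape[1]) - 1L)
    for (j in seq_len(shape[2]) - 1L)
      for (k in seq_len(shape[3]) - 1L) {
        k_emit <- if (g$flip_slices) shape[3] - 1L - k else k
        got <- dicomnav:::slice_geometry_position(g, i, j, k_emit)
        want <- affine_voxel_lps(affine, i, j, k)
        worst <- max(worst, max(abs(got - want)))
      }
  expect_lt(worst, tol)
  invisible(g)
}

test_that("identity affine decomposes to unit spacings and exact positions", {
  g <- expect_voxel_centre_agreement(diag(4), c(4L, 4L, 4L))
  expect_equal(g$pixel_spacing, c(1, 1))
  expect_equal(g$slice_spacing, 1)
  expect_false(g$flip_slices)
})

test_that("anisotropic scaling maps column norms onto the spacings", {
  af <- diag(c(2, 3, 4, 1))
  g <- expect_voxel_centre_agreement(af, c(3L, 4L, 5L))
  # DICOM pixel spacing is (between-rows, between-columns)
  expect_equal(g$pixel_spacing, c(3, 2))
  expect_equal(g$slice_spacing, 4)
})

test_that("in-plane rotation reconstructs voxel centres within 1e-3 mm", {
  th <- 0.2
  R <- rbind(c(cos(th), -sin(th), 0, 5),
             c(sin(th), cos(th), 0, -7),
             c(0, 0, 1, 2),
             c(0, 0, 0, 1))
  expect_voxel_centre_agreement(R, c(4L, 4L, 3L))
})

test_that("random orthogonal affines reconstruct within 1e-3 mm", {
  for (seed in 1:15) {
    af <- rand_orthogonal_affine(seed, left_handed = seed %% 3 == 0)
    g <- expect_voxel_centre_agreement(af, c(4L, 3L, 5L))
    # direction cosines unit-norm and orthogonal
    r <- g$orientation[1:3]; c2 <- g$orientation[4:6]
    expect_equal(sqrt(sum(r^2)), 1, tolerance = 1e-6)
    expect_equal(sqrt(sum(c2^2)), 1, tolerance = 1e-6)
    expect_lt(abs(sum(r * c2)), 1e-6)
    # consecutive positions separated by slice_spacing along the normal
    if (nrow(g$positions) > 1) {
      steps <- diff(g$positions)
      expect_equal(steps %*% g$normal,
                   matrix(g$slice_spacing, nrow(steps)), tolerance = 1e-6)
    }
  }
})

test_that("sheared affines are refused rather than resampled", {
  af <- diag(4)
  af[1, 2] <- 0.05  # strong shear between first and second axes
  expect_error(affine_to_slice_geometry(af, c(4L, 4L, 4L)),
               class = "dicomnav_geometry_error")
})

test_that("degenerate affines are rejected", {
  af <- diag(4); af[2, 2] <- 0
  expect_error(affine_to_slice_geometry(af, c(4L, 4L, 4L)),
               class = "dicomnav_input_error")
  expect_error(affine_to_slice_geometry(diag(3), c(4L, 4L, 4L)),
               class = "dicomnav_input_error")
})

test_that("geometry matching compares shape, spacing and orientation only", {
  af <- rand_orthogonal_affine(5)
  shifted <- af; shifted[1:3, 4] <- shifted[1:3, 4] + c(10, -4, 2)
  scaled <- af; scaled[1:3, 1:3] <- 2 * scaled[1:3, 1:3]
  expect_true(dicomnav:::geometry_matches(af, c(8, 8, 4), shifted, c(8, 8, 4)))
  expect_false(dicomnav:::geometry_matches(af, c(8, 8, 4), scaled, c(8, 8, 4)))
  expect_false(dicomnav:::geometry_matches(af, c(8, 8, 4), af, c(8, 8, 5)))
})

test_that("NIfTI volumes round trip through write and read with their affine", {
  af <- rand_orthogonal_affine(9)
  vol <- image_volume(array(stats::rnorm(60), c(5, 4, 3)), af)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti_volume(vol, f)
  back <- read_nifti_volume(f)
  expect_equal(back$affine, af, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(back$data, vol$data, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("4D multi-component NIfTI input is refused with the documented message", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4, 2))), f)
  expect_error(read_nifti_volume(f), "not supported",
               class = "dicomnav_input_error")
  # trailing singleton dimension is squeezed, not refused
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4, 1))), f2)
  expect_equal(dim(read_nifti_volume(f2)$data), c(4L, 4L, 4L))
})
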