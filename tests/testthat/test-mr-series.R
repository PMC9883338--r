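# Template attribute copying and MR series emission.

test_that("template attributes are copied verbatim and absences tolerated", {
  dir <- withr::local_tempdir()
  tpl <- file.path(dir, "t.dcm")
  make_minimal_template_dicom(list(PatientID = "TEST01",
                                   PatientName = "Doe^Jane",
                                   InstitutionName = "Some Hospital"), tpl)
  meta <- load_template(tpl)
  expect_identical(meta$attributes$PatientID, "TEST01")
  expect_identical(meta$attributes$PatientName, "Doe^Jane")
  # accession number absent from the template: simply omitted, no failure
  expect_null(meta$attributes$AccessionNumber)
})

test_that("a text file renamed .dcm is a format error", {
  f <- withr::local_tempfile(fileext = ".dcm")
  writeLines("definitely not dicom, but padded to be long enough to parse....",
             f)
  expect_error(load_template(f), class = "dicomnav_format_error")
})

test_that("integer volumes decode exactly through an independent DICOM reader", {
  setup <- make_test_setup()
  vol <- image_volume(array(0:26, c(3, 3, 3)), diag(4))
  ser <- volume_to_mr_series(vol, setup$meta, setup$ctx)
  expect_length(ser$instances, 3L)
  dir <- withr::local_tempdir()
  paths <- write_mr_series(ser, dir)
  recovered <- array(NA_real_, c(3, 3, 3))
  for (k in 1:3) {
    info <- oracle("mr-info", paths[k], "--pixels")
    # pydicom flattens row-major: column index fastest = our first axis
    recovered[, , k] <- array(info$decoded, c(3, 3))
    expect_equal(info$instance_number, k)
  }
  expect_equal(recovered, vol$data)
  # template attributes present on every instance
  v <- oracle("validate", paths[2])
  expect_true(v$ok)
})

test_that("constant volumes store zero with slope 1 and intercept the constant", {
  enc <- dicomnav:::compute_intensity_encoding(array(42, c(2, 2, 2)))
  expect_equal(enc$slope, 1)
  expect_equal(enc$intercept, 42)
  stored <- dicomnav:::apply_intensity_encoding(array(42, c(2, 2, 2)), enc)
  expect_true(all(stored == 0L))
})

test_that("4D input is refused, quoting the unsupported-input contract", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(3, 3, 3, 2))), f)
  err <- expect_error(read_nifti_volume(f), class = "dicomnav_input_error")
  expect_match(conditionMessage(err),
               "fMRI time series or raw diffusion data, are not supported")
})

test_that("intensity round trip: integers exact, floats within slope/2", {
  set.seed(21)
  # integer-valued with range < 2^16: exact
  v_int <- array(sample(-500:500, 64, replace = TRUE), c(4, 4, 4))
  enc <- dicomnav:::compute_intensity_encoding(v_int)
  stored <- dicomnav:::apply_intensity_encoding(v_int, enc)
  expect_equal(stored * enc$slope + enc$intercept, v_int)
  # floats: bounded by slope/2
  for (i in 1:5) {
    v <- array(stats::rnorm(64, sd = 10^i), c(4, 4, 4))
    enc <- dicomnav:::compute_intensity_encoding(v)
    stored <- dicomnav:::apply_intensity_encoding(v, enc)
    expect_lte(max(abs(stored * enc$slope + enc$intercept - v)),
               enc$slope / 2 + 1e-12)
  }
  # wide-range integers fall back to scaling but stay within slope/2
  v_wide <- array(c(0, 1, 2, 200000), c(2, 2, 1, 1))
  enc <- dicomnav:::compute_intensity_encoding(v_wide)
  expect_false(enc$integer_exact)
})

test_that("emitted instances reproduce the source geometry within 1e-3 mm", {
  setup <- make_test_setup()
  af <- rand_orthogonal_affine(31)
  vol <- image_volume(array(stats::rnorm(48), c(4, 4, 3)), af)
  ser <- volume_to_mr_series(vol, setup$meta, setup$ctx)
  dir <- withr::local_tempdir()
  paths <- write_mr_series(ser, dir)
  for (k in seq_along(paths)) {
    info <- oracle("mr-info", paths[k])
    worst <- 0
    for (i in 0:3) for (j in 0:3) {
      got <- info$ipp + info$iop[1:3] * info$pixel_spacing[2] * i +
        info$iop[4:6] * info$pixel_spacing[1] * j
      want <- affine_voxel_lps(af, i, j, k - 1)
      worst <- max(worst, max(abs(got - want)))
    }
    expect_lt(worst, 1e-3)
  }
})

test_that("UIDs are shared within a run and reproducible under a seed", {
  dir <- withr::local_tempdir()
  tpl <- file.path(dir, "t.dcm")
  make_minimal_template_dicom(list(PatientID = "X"), tpl)
  meta <- load_template(tpl)
  run <- function(seed) {
    ctx <- series_context(rng_seed = seed)
    ctx$study_uid <- new_uid(ctx)
    v1 <- image_volume(array(1:8, c(2, 2, 2)), diag(4))
    v2 <- image_volume(array(8:1, c(2, 2, 2)), diag(4))
    s1 <- volume_to_mr_series(v1, meta, ctx)
    s2 <- volume_to_mr_series(v2, meta, ctx)
    list(s1 = s1, s2 = s2, ctx = ctx)
  }
  a <- run(77L); b <- run(77L); c3 <- run(78L)
  # distinct series UIDs per input image, shared study and frame of reference
  expect_false(a$s1$series_uid == a$s2$series_uid)
  uid_of <- function(s, kw) dicomnav:::dcm_find(s$instances[[1]], kw)$value
  expect_identical(uid_of(a$s1, "FrameOfReferenceUID"),
                   uid_of(a$s2, "FrameOfReferenceUID"))
  expect_identical(uid_of(a$s1, "StudyInstanceUID"),
                   uid_of(a$s2, "StudyInstanceUID"))
  # reproducible with the same seed, different otherwise
  expect_identical(a$s1$instance_uids, b$s1$instance_uids)
  expect_false(any(a$s1$instance_uids %in% c3$s1$instance_uids))
})

test_that("generated UIDs are well-formed", {
  ctx <- series_context(rng_seed = 12L)
  for (i in 1:50) {
    uid <- new_uid(ctx)
    expect_lte(nchar(uid), 64L)
    expect_match(uid, "^[0-9]+(\\.[0-9]+)+$")
    # no leading zeros in any component
    comps <- strsplit(uid, ".", fixed = TRUE)[[1]]
    expect_false(any(nchar(comps) > 1 & startsWith(comps, "0")))
  }
})
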