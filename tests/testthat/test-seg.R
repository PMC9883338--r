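# Label maps -> DICOM Segmentation objects.

test_that("the segment palette is deterministic, distinct and capped at 30", {
  expect_equal(nrow(assign_segment_colors(1)), 1L)
  p30 <- assign_segment_colors(30)
  expect_equal(nrow(p30), 30L)
  expect_false(any(duplicated(p30)))                 # pairwise distinct RGB
  expect_false(any(duplicated(attr(p30, "cielab")))) # and in CIELab encoding
  expect_identical(p30, assign_segment_colors(30))   # identical across calls
  err <- expect_error(assign_segment_colors(31),
                      class = "dicomnav_input_error")
  expect_match(conditionMessage(err), "at most 30 labels")
  expect_error(assign_segment_colors(0), class = "dicomnav_input_error")
})

test_that("label map validation refuses rounding, negatives and >30 labels", {
  expect_error(label_map(array(c(0, 1.5), c(2, 1, 1)), diag(4)),
               "never rounded", class = "dicomnav_input_error")
  expect_error(label_map(array(c(0, -2), c(2, 1, 1)), diag(4)),
               class = "dicomnav_input_error")
  too_many <- array(0, c(4, 4, 4))
  too_many[seq_len(31)] <- 1:31
  expect_error(label_map(too_many, diag(4)), "at most 30",
               class = "dicomnav_input_error")
  expect_error(label_map(array(70000, c(1, 1, 1)), diag(4)),
               class = "dicomnav_input_error")
})

test_that("two disjoint blobs become segments 1 and 2 and recompose exactly", {
  setup <- make_test_setup()
  a <- array(0, c(8, 8, 4))
  a[2:3, 2:3, 2] <- 3
  a[6:7, 6:7, 3] <- 7
  lm <- label_map(a, diag(4))
  ref <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(8, 8, 4))),
                             setup$meta, setup$ctx)
  seg <- labelmap_to_seg(lm, ref, setup$meta, setup$ctx)
  expect_equal(seg$segments$segment_number, 1:2)
  expect_equal(seg$segments$label_value, c(3L, 7L))
  path <- write_seg_object(seg, withr::local_tempdir())

  # independent pydicom recomposition
  r <- oracle("seg-recompose", path)
  expect_equal(r$n_segments, 2L)
  expect_equal(sort(r$segment_values), c(3L, 7L))
  geom <- affine_to_slice_geometry(diag(4), c(8, 8, 4))
  k_emit <- apply(r$frame_positions, 1, function(p)
    which.min(rowSums(sweep(geom$positions, 2, p)^2)))
  arr <- array(0L, c(8, 8, 4))
  for (i in seq_len(nrow(r$voxels))) {
    v <- r$voxels[i, ]
    arr[v[2] + 1, v[3] + 1, k_emit[v[4] + 1]] <- v[1]
  }
  expect_identical(arr, array(as.integer(a), dim(a)))
  # every frame references an instance of the matched MR series
  expect_true(all(r$frame_source_instances %in% ref$instance_uids))
  # and the file passes the independent conformance check
  v <- oracle("validate", path)
  expect_true(v$ok)
})

test_that("a geometry mismatch against every reference is refused", {
  setup <- make_test_setup()
  a <- array(0, c(8, 8, 4)); a[3, 3, 2] <- 1
  lm <- label_map(a, diag(c(2, 2, 2, 1)))  # scaled x2 vs unscaled reference
  ref <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(8, 8, 4))),
                             setup$meta, setup$ctx)
  expect_error(labelmap_to_seg(lm, ref, setup$meta, setup$ctx),
               class = "dicomnav_geometry_error")
})

test_that("a single labelled voxel yields one segment and one frame", {
  setup <- make_test_setup()
  a <- array(0, c(6, 6, 3)); a[4, 2, 2] <- 1
  lm <- label_map(a, diag(4))
  ref <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(6, 6, 3))),
                             setup$meta, setup$ctx)
  seg <- labelmap_to_seg(lm, ref, setup$meta, setup$ctx)
  expect_equal(nrow(seg$segments), 1L)
  expect_equal(nrow(seg$frames), 1L)
  path <- write_seg_object(seg, withr::local_tempdir())
  back <- seg_to_labelmap(path, diag(4), c(6, 6, 3))
  expect_identical(back, array(as.integer(a), dim(a)))
})

test_that("an all-zero label map is refused as empty", {
  setup <- make_test_setup()
  lm <- label_map(array(0, c(4, 4, 2)), diag(4))
  ref <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(4, 4, 2))),
                             setup$meta, setup$ctx)
  expect_error(labelmap_to_seg(lm, ref, setup$meta, setup$ctx),
               "empty", class = "dicomnav_input_error")
})

test_that("random blob fixtures round trip losslessly across label counts", {
  setup <- make_test_setup()
  dir <- withr::local_tempdir()
  for (case in list(list(n = 1, shape = c(16, 16, 8), seed = 1),
                    list(n = 5, shape = c(24, 24, 12), seed = 2),
                    list(n = 13, shape = c(32, 32, 16), seed = 3),
                    list(n = 30, shape = c(32, 32, 32), seed = 4))) {
    af <- rand_orthogonal_affine(case$seed, left_handed = case$n %% 2 == 0,
                                 scale_range = c(0.8, 1.5))
    spec <- phantom_spec(case$shape, affine = af, seed = case$seed)
    # permute values so segment ordering is exercised, not just 1..n
    values <- sample(seq(2, 90, by = 3))[seq_len(case$n)]
    lm <- make_label_blobs(case$n, spec, values = sort(values))
    ref <- volume_to_mr_series(make_phantom_volume(spec), setup$meta,
                               setup$ctx)
    seg <- labelmap_to_seg(lm, ref, setup$meta, setup$ctx)
    expect_equal(nrow(seg$segments), case$n)
    expect_false(any(duplicated(seg$segments[, c("red", "green", "blue")])))
    path <- write_seg_object(seg, file.path(dir, paste0("c", case$n)))
    back <- seg_to_labelmap(path, af, case$shape)
    expect_identical(back, array(as.integer(lm$data), dim(lm$data)))
  }
})

test_that("segment ordering follows ascending label value regardless of voxel order", {
  setup <- make_test_setup()
  a <- array(0, c(6, 6, 2))
  a[1, 1, 1] <- 9   # first in memory, largest value
  a[6, 6, 2] <- 2
  lm <- label_map(a, diag(4))
  ref <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(6, 6, 2))),
                             setup$meta, setup$ctx)
  seg <- labelmap_to_seg(lm, ref, setup$meta, setup$ctx)
  expect_equal(seg$segments$label_value, c(2L, 9L))
  expect_equal(seg$segments$label_text, c("Label 2", "Label 9"))
})

test_that("custom segment label text can be supplied", {
  setup <- make_test_setup()
  a <- array(0, c(4, 4, 2)); a[2, 2, 1] <- 5
  lm <- label_map(a, diag(4))
  ref <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(4, 4, 2))),
                             setup$meta, setup$ctx)
  seg <- labelmap_to_seg(lm, ref, setup$meta, setup$ctx,
                         segment_labels = c("5" = "tumour"))
  expect_equal(seg$segments$label_text, "tumour")
})
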