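# Tractograms -> DICOM Surface Segmentation objects.

test_that("a single streamline is stored as LPS points with 1-based indices", {
  setup <- make_test_setup()
  ref <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(6, 6, 4))),
                             setup$meta, setup$ctx)
  tr <- tractogram(list(rbind(c(0, 0, 0), c(10, 0, 0))))
  surf <- tractogram_to_surface(tr, ref, setup$meta, setup$ctx)
  path <- write_surface_object(surf, withr::local_tempdir())
  si <- oracle("surface-info", path)
  expect_equal(si$n_points, 2L)
  expect_equal(si$points, c(0, 0, 0, -10, 0, 0))
  expect_equal(as_runs(si$runs)[[1]], c(1L, 2L))
  expect_equal(si$referenced_series, ref$series_uid)
  v <- oracle("validate", path)
  expect_true(v$ok)
})

test_that("streamline runs partition the point list in input order", {
  setup <- make_test_setup()
  ref <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(6, 6, 4))),
                             setup$meta, setup$ctx)
  tr <- tractogram(list(rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)),
                        rbind(c(-1, -2, -3), c(-4, -5, -6))))
  surf <- tractogram_to_surface(tr, ref, setup$meta, setup$ctx)
  path <- write_surface_object(surf, withr::local_tempdir())
  si <- oracle("surface-info", path)
  expect_equal(si$n_points, 5L)
  runs <- as_runs(si$runs)
  expect_equal(runs[[1]], 1:3)
  expect_equal(runs[[2]], 4:5)
  expect_identical(sort(unlist(runs)), 1:5)  # exact partition of [1, N]
})

test_that("tck -> surface -> tck reproduces points at float32 precision", {
  setup <- make_test_setup()
  ref <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(6, 6, 4))),
                             setup$meta, setup$ctx)
  dir <- withr::local_tempdir()
  for (seed in c(2L, 12L)) {
    tg <- make_helical_tracts(25L, seed = seed)
    f <- file.path(dir, sprintf("in%d.tck", seed))
    write_tck(tg, f)
    tg32 <- read_tck(f)
    surf <- tractogram_to_surface(tg32, ref, setup$meta, setup$ctx)
    path <- write_surface_object(surf, file.path(dir, paste0("s", seed)))
    back <- surface_to_tractogram(path)
    expect_length(back, length(tg32))
    err <- max(mapply(function(a, b) max(abs(a - b)),
                      back$streamlines, tg32$streamlines))
    expect_identical(err, 0)  # float32-representable values survive exactly
    # order and point counts conserved
    expect_identical(lapply(back$streamlines, nrow),
                     lapply(tg32$streamlines, nrow))
    f2 <- file.path(dir, sprintf("out%d.tck", seed))
    write_tck(back, f2)
    expect_identical(read_tck(f2)$streamlines, tg32$streamlines)
  }
})

test_that("single-point streamlines survive the surface round trip", {
  setup <- make_test_setup()
  ref <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(6, 6, 4))),
                             setup$meta, setup$ctx)
  tr <- tractogram(list(matrix(c(5, -3, 2), 1)))
  surf <- tractogram_to_surface(tr, ref, setup$meta, setup$ctx)
  path <- write_surface_object(surf, withr::local_tempdir())
  si <- oracle("surface-info", path)
  expect_equal(si$n_points, 1L)
  expect_equal(unlist(as_runs(si$runs)), 1L)
  back <- surface_to_tractogram(path)
  expect_equal(back$streamlines[[1]], tr$streamlines[[1]])
})

test_that("empty tractograms and zero-based indices are refused", {
  setup <- make_test_setup()
  ref <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(6, 6, 4))),
                             setup$meta, setup$ctx)
  expect_error(tractogram_to_surface(tractogram(), ref, setup$meta, setup$ctx),
               class = "dicomnav_input_error")
  # craft an object whose line primitive uses a 0-based index
  tr <- tractogram(list(rbind(c(0, 0, 0), c(1, 1, 1))))
  surf <- tractogram_to_surface(tr, ref, setup$meta, setup$ctx)
  bad_idx <- dicomnav:::raw_from_uint32(c(0L, 1L))  # index 0 violates 1-based rule
  ds <- surf$dataset
  for (i in seq_along(ds)) {
    if (identical(ds[[i]]$keyword, "SurfaceSequence")) {
      prim <- ds[[i]]$value[[1]]
      for (j in seq_along(prim)) {
        if (identical(prim[[j]]$keyword, "SurfaceMeshPrimitivesSequence")) {
          line <- prim[[j]]$value[[1]]
          for (l in seq_along(line)) {
            if (identical(line[[l]]$keyword, "LineSequence"))
              line[[l]]$value[[1]][[1]]$value <- bad_idx
          }
          prim[[j]]$value[[1]] <- line
        }
      }
      ds[[i]]$value[[1]] <- prim
    }
  }
  f <- withr::local_tempfile(fileext = ".dcm")
  dicomnav:::write_dicom_file(ds, f)
  expect_error(surface_to_tractogram(f), "1-based",
               class = "dicomnav_corrupt_error")
})

test_that("tract objects always derive from the first structural series", {
  setup <- make_test_setup()
  ref1 <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(6, 6, 4))),
                              setup$meta, setup$ctx)
  ref2 <- volume_to_mr_series(make_phantom_volume(phantom_spec(c(6, 6, 4),
                                                               seed = 2)),
                              setup$meta, setup$ctx)
  tr <- make_helical_tracts(3L, seed = 5)
  surf <- tractogram_to_surface(tr, ref1, setup$meta, setup$ctx)
  expect_identical(surf$reference_series_uid, ref1$series_uid)
  expect_false(surf$reference_series_uid == ref2$series_uid)
})
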