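# MRtrix tck reading and writing.

write_raw_tck <- function(path, triplets, datatype = "Float32LE",
                          count = NULL, extra_header = character()) {
  # build a tck file byte-by-byte from the published format description
  lines <- c("mrtrix tracks", extra_header,
             paste0("datatype: ", datatype),
             if (!is.null(count)) paste0("count: ", count))
  offset <- 0L
  repeat {
    hdr <- paste0(paste(c(lines, paste0("file: . ", offset), "END"),
                        collapse = "\n"), "\n")
    if (nchar(hdr, type = "bytes") == offset) break
    offset <- nchar(hdr, type = "bytes")
  }
  size <- if (grepl("Float32", datatype)) 4L else 8L
  endian <- if (grepl("BE$", datatype)) "big" else "little"
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(t(triplets)), con, size = size, endian = endian)
  invisible(path)
}

test_that("a hand-built tck byte stream is read back point for point", {
  f <- withr::local_tempfile(fileext = ".tck")
  trip <- rbind(c(0, 0, 0), c(1, 1, 1), c(NaN, NaN, NaN), c(Inf, Inf, Inf))
  write_raw_tck(f, trip, count = 1)
  tg <- read_tck(f)
  expect_length(tg, 1L)
  expect_equal(tg$streamlines[[1]], rbind(c(0, 0, 0), c(1, 1, 1)))
  # independent reference reader agrees
  nb <- oracle("read-tck", f)
  expect_equal(nb$count, 1L)
  expect_equal(nb$points, rbind(c(0, 0, 0), c(1, 1, 1)), ignore_attr = TRUE)
})

test_that("count 0 with only the Inf terminator yields an empty tractogram", {
  f <- withr::local_tempfile(fileext = ".tck")
  write_raw_tck(f, rbind(c(Inf, Inf, Inf)), count = 0)
  tg <- read_tck(f)
  expect_length(tg, 0L)
})

test_that("all supported datatypes decode to the same coordinates", {
  pts <- rbind(c(1.5, -2.25, 3), c(4, 5, 6.125))
  trip <- rbind(pts, c(NaN, NaN, NaN), c(Inf, Inf, Inf))
  for (dt in c("Float32LE", "Float32BE", "Float64LE", "Float64BE")) {
    f <- withr::local_tempfile(fileext = ".tck")
    write_raw_tck(f, trip, datatype = dt, count = 1)
    tg <- read_tck(f)
    expect_equal(tg$streamlines[[1]], pts, ignore_attr = TRUE,
                 tolerance = 1e-6)
  }
  f <- withr::local_tempfile(fileext = ".tck")
  write_raw_tck(f, trip, datatype = "UInt32LE", count = 1)
  expect_error(read_tck(f), class = "dicomnav_format_error")
})

test_that("read-write round trip is the identity at float32 precision", {
  for (seed in c(1L, 7L, 23L)) {
    tg <- make_helical_tracts(10L, seed = seed)
    # store at float32 first so the round trip is exact, not just close
    f1 <- withr::local_tempfile(fileext = ".tck")
    write_tck(tg, f1)
    tg32 <- read_tck(f1)
    f2 <- withr::local_tempfile(fileext = ".tck")
    write_tck(tg32, f2)
    back <- read_tck(f2)
    expect_length(back, length(tg32))
    expect_identical(lapply(back$streamlines, dim),
                     lapply(tg32$streamlines, dim))
    expect_identical(back$streamlines, tg32$streamlines)
    # total point count conserved through read and write
    expect_identical(sum(vapply(back$streamlines, nrow, 0L)),
                     sum(vapply(tg$streamlines, nrow, 0L)))
  }
})

test_that("written files agree with the independent reference reader", {
  tg <- make_helical_tracts(8L, seed = 11L)
  f <- withr::local_tempfile(fileext = ".tck")
  write_tck(tg, f)
  nb <- oracle("read-tck", f)
  expect_equal(nb$count, 8L)
  expect_equal(nb$lengths, vapply(tg$streamlines, nrow, 0L))
  ours <- read_tck(f)
  expect_equal(nb$points, do.call(rbind, ours$streamlines),
               ignore_attr = TRUE)  # exact at matching (float32) precision
})

test_that("single-point streamlines are preserved, not dropped", {
  tg <- tractogram(list(matrix(c(1, 2, 3), 1), rbind(c(0, 0, 0), c(1, 0, 0))))
  f <- withr::local_tempfile(fileext = ".tck")
  write_tck(tg, f)
  back <- read_tck(f)
  expect_length(back, 2L)
  expect_equal(nrow(back$streamlines[[1]]), 1L)
})

test_that("count mismatches error in strict mode and warn in lenient mode", {
  f <- withr::local_tempfile(fileext = ".tck")
  trip <- rbind(c(0, 0, 0), c(1, 1, 1), c(NaN, NaN, NaN), c(Inf, Inf, Inf))
  write_raw_tck(f, trip, count = 5)
  expect_error(read_tck(f), class = "dicomnav_corrupt_error")
  expect_warning(tg <- read_tck(f, strict = FALSE), "count mismatch")
  expect_length(tg, 1L)
})

test_that("malformed files are refused with informative errors", {
  f <- withr::local_tempfile(fileext = ".tck")
  writeLines("not a tck file", f)
  expect_error(read_tck(f), class = "dicomnav_format_error")
  # binary truncated before the Inf terminator
  f2 <- withr::local_tempfile(fileext = ".tck")
  write_raw_tck(f2, rbind(c(0, 0, 0), c(1, 1, 1)), count = 1)
  expect_error(read_tck(f2), class = "dicomnav_corrupt_error")
  expect_error(write_tck(tractogram(list(rbind(c(0, 0, NA_real_)))),
                         withr::local_tempfile()),
               class = "dicomnav_input_error")
})

test_that("header keys are preserved verbatim through a round trip", {
  f <- withr::local_tempfile(fileext = ".tck")
  write_raw_tck(f, rbind(c(1, 2, 3), c(NaN, NaN, NaN), c(Inf, Inf, Inf)),
                count = 1,
                extra_header = c("step_size: 0.5", "MyTool_version: 3.2"))
  tg <- read_tck(f)
  expect_equal(tg$header[["step_size"]], "0.5")
  expect_equal(tg$header[["MyTool_version"]], "3.2")
  f2 <- withr::local_tempfile(fileext = ".tck")
  write_tck(tg, f2)
  expect_equal(read_tck(f2)$header[["MyTool_version"]], "3.2")
})
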