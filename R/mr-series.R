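# Structural volumes become classic single-frame MR Image Storage series:
# one Part-10 file per slice, all slices sharing a fresh series UID and the
# run's common frame of reference.  Classic (not Enhanced) MR maximises
# importability by the navigation suites this converter targets.

# Map floating NIfTI intensities onto unsigned 16-bit stored values.
# Integer-valued data with range <= 65535 uses slope 1 / intercept min, so
# typical integer volumes survive exactly; other data is scaled min -> 0,
# max -> 65535 with slope = range/65535, giving error <= slope/2.  Constant
# volumes store 0 with slope 1 / intercept = the constant.  NaN voxels are
# mapped to the minimum and counted.
compute_intensity_encoding <- function(data) {
  v <- as.numeric(data)
  n_nan <- sum(is.nan(v))
  finite <- v[is.finite(v)]
  if (length(finite) == 0L)
    stop_input("volume contains no finite voxel values")
  lo <- min(finite); hi <- max(finite)
  if (hi == lo) {
    list(slope = 1, intercept = lo, n_nan = n_nan, integer_exact = TRUE)
  } else if (all(finite == round(finite)) && (hi - lo) <= 65535) {
    list(slope = 1, intercept = lo, n_nan = n_nan, integer_exact = TRUE)
  } else {
    list(slope = (hi - lo) / 65535, intercept = lo, n_nan = n_nan,
         integer_exact = FALSE)
  }
}

apply_intensity_encoding <- function(data, enc) {
  v <- data
  v[!is.finite(v)] <- enc$intercept
  stored <- round((v - enc$intercept) / enc$slope)
  stored[stored < 0] <- 0
  stored[stored > 65535] <- 65535
  array(as.integer(stored), dim = dim(data))
}

#' Convert an image volume to a classic MR DICOM series
#'
#' Produces one single-frame MR Image Storage instance per slice.  All
#' instances share one newly minted series UID, the context's study UID and
#' common frame-of-reference UID, and the template's patient/institution
#' attributes.  Instance numbers ascend along the emitted slice axis,
#' consistent with the per-slice plane positions.  Pixel values are stored
#' as unsigned 16-bit integers, decodable through the emitted
#' RescaleSlope/RescaleIntercept.
#'
#' @param vol an [image_volume()] (3D; 4D input is refused upstream).
#' @param meta a [load_template()] result.
#' @param ctx a [series_context()] with `study_uid` set.
#' @param series_description free-text series description; defaults to the
#'   source file name.
#' @return an object of class `mr_series`: list with `series_uid`,
#'   `series_number`, `sop_class`, `instance_uids`, `instances` (list of
#'   DICOM datasets), `geometry`, `encoding`.
#' @export
volume_to_mr_series <- function(vol, meta, ctx, series_description = NULL) {
  stopifnot(inherits(vol, "image_volume"), inherits(ctx, "series_context"))
  if (is.null(ctx$study_uid))
    stop_input("series context has no study UID; load a template first")
  geom <- affine_to_slice_geometry(vol$affine, dim(vol$data))
  enc <- compute_intensity_encoding(vol$data)
  stored <- apply_intensity_encoding(vol$data, enc)
  if (geom$flip_slices)
    stored <- stored[, , rev(seq_len(dim(stored)[3])), drop = FALSE]
  if (is.null(series_description)) {
    series_description <- if (is.na(vol$source_path)) "converted volume"
      else basename(vol$source_path)
  }
  series_uid <- new_uid(ctx)
  series_number <- next_series_number(ctx)
  clock <- ctx_date_time(ctx)
  n_slices <- dim(stored)[3]
  instance_uids <- character(n_slices)
  instances <- vector("list", n_slices)

  for (k in seq_len(n_slices)) {
    instance_uids[k] <- new_uid(ctx)
    # DICOM pixel order: rows of the image in sequence; with the first voxel
    # axis as the DICOM column axis, R's column-major slice layout is
    # already (column fastest, row next)
    pix <- raw_from_uint16(as.vector(stored[, , k]))
    ds <- dcm_ds(
      SOPClassUID = DCM_UID$mr_image_storage,
      SOPInstanceUID = instance_uids[k],
      StudyInstanceUID = ctx$study_uid,
      SeriesInstanceUID = series_uid,
      FrameOfReferenceUID = ctx$frame_of_reference_uid,
      Modality = "MR",
      ImageType = c("DERIVED", "SECONDARY"),
      SpecificCharacterSet = "ISO_IR 100",
      SeriesNumber = series_number,
      InstanceNumber = k,
      SeriesDescription = series_description,
      SeriesDate = clock$date,
      SeriesTime = clock$time,
      ContentDate = clock$date,
      ContentTime = clock$time,
      Manufacturer = "dicomnav",
      ManufacturerModelName = "dicomnav converter",
      SoftwareVersions = .IMPLEMENTATION_VERSION,
      PositionReferenceIndicator = character(0),
      ScanningSequence = "RM",
      SequenceVariant = "NONE",
      ScanOptions = character(0),
      MRAcquisitionType = "3D",
      RepetitionTime = character(0),
      EchoTime = character(0),
      EchoTrainLength = character(0),
      Rows = unname(geom$shape["rows"]),
      Columns = unname(geom$shape["columns"]),
      PixelSpacing = geom$pixel_spacing,
      SliceThickness = geom$slice_spacing,
      SpacingBetweenSlices = geom$slice_spacing,
      ImagePositionPatient = geom$positions[k, ],
      ImageOrientationPatient = geom$orientation,
      SamplesPerPixel = 1L,
      PhotometricInterpretation = "MONOCHROME2",
      BitsAllocated = 16L,
      BitsStored = 16L,
      HighBit = 15L,
      PixelRepresentation = 0L,
      RescaleIntercept = enc$intercept,
      RescaleSlope = enc$slope,
      RescaleType = "US",
      PixelData = pix
    )
    ds <- apply_template(ds, meta)
    instances[[k]] <- ds
  }

  structure(list(
    series_uid = series_uid,
    series_number = series_number,
    sop_class = DCM_UID$mr_image_storage,
    instance_uids = instance_uids,
    instances = instances,
    geometry = geom,
    affine = vol$affine,
    shape = dim(vol$data),
    encoding = enc,
    source_path = vol$source_path
  ), class = "mr_series")
}

#' Write an MR series to disk
#'
#' One Part-10 file per slice, named
#' `<series number>/MR.<instance number>.dcm` inside `outdir`.
#'
#' @param series an `mr_series` from [volume_to_mr_series()].
#' @param outdir output directory (created if needed).
#' @return character vector of written file paths.
#' @export
write_mr_series <- function(series, outdir) {
  stopifnot(inherits(series, "mr_series"))
  dir <- file.path(outdir, series$series_number)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(series$instances))
  for (k in seq_along(series$instances)) {
    paths[k] <- file.path(dir, sprintf("MR.%d.dcm", k))
    write_dicom_file(series$instances[[k]], paths[k],
                     transfer_syntax = DCM_UID$explicit_vr_le)
  }
  paths
}
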