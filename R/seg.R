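# Integer label maps become DICOM Segmentation objects: one binary segment
# per distinct nonzero label value (at most 30, each with a distinct
# color), one run-length-encoded frame per (segment, occupied slice), and
# per-frame derivation references to the geometry-matched MR series.

.CODE_SOURCE_PURPOSE <- function() list(dcm_ds(
  CodeValue = "121322", CodingSchemeDesignator = "DCM",
  CodeMeaning = "Source image for image processing operation"))
.CODE_SEGMENTATION <- function() list(dcm_ds(
  CodeValue = "113076", CodingSchemeDesignator = "DCM",
  CodeMeaning = "Segmentation"))
.CODE_TISSUE <- function() list(dcm_ds(
  CodeValue = "T-D0050", CodingSchemeDesignator = "SRT",
  CodeMeaning = "Tissue"))

#' Construct a label map
#'
#' Validates an integer label volume: non-negative integer voxel values
#' representable in 16 bits, at most 30 distinct nonzero values.
#' Non-integer voxel values are rejected, never rounded, since rounding
#' could silently merge structures.
#'
#' @param data 3D array of non-negative integers.
#' @param affine 4x4 voxel-to-RAS-mm matrix.
#' @param source_path provenance string.
#' @return an object of class `label_map` (also an `image_volume`).
#' @export
label_map <- function(data, affine, source_path = NA_character_) {
  vol <- image_volume(data, affine, intent = "label",
                      source_path = source_path)
  v <- vol$data
  if (any(!is.finite(v)))
    stop_input("label map contains non-finite voxel values")
  if (any(v != round(v)))
    stop_input("label map contains non-integer voxel values; ",
               "labels are never rounded")
  if (any(v < 0))
    stop_input("label map contains negative values")
  if (max(v) > 65535)
    stop_input("label values must be representable in 16 bits")
  values <- sort(unique(v[v != 0]))
  if (length(values) > 30L)
    stop_input("too many labels: label map has ", length(values),
               " distinct nonzero values but label images support at most ",
               "30 labels")
  vol$label_values <- as.integer(values)
  class(vol) <- c("label_map", class(vol))
  vol
}

#' Read a NIfTI label image
#'
#' @param path path to a `.nii`/`.nii.gz` integer label image.
#' @return a [label_map()].
#' @export
read_label_map <- function(path) {
  vol <- read_nifti_volume(path, intent = "label")
  label_map(vol$data, vol$affine, source_path = path)
}

#' Convert a label map to a DICOM Segmentation object
#'
#' Emits a Segmentation Storage object (modality SEG) in the RLE Lossless
#' transfer syntax.  Each distinct nonzero label value becomes one segment
#' (segment numbers consecutive from 1 in ascending label-value order),
#' with a distinct display color from the package palette.  One binary
#' frame is emitted per (segment, occupied slice); empty slices produce no
#' frame.  Every frame carries a derivation reference to the matching
#' instance of the geometry-matched MR reference series, and the object
#' shares the run's frame-of-reference UID.
#'
#' @param labels a [label_map()].
#' @param reference the `mr_series` whose grid matches the label map
#'   (shape, spacing and orientation within 1e-3; coregistration is assumed
#'   and never checked).
#' @param meta a [load_template()] result.
#' @param ctx a [series_context()].
#' @param segment_labels optional named character vector mapping label
#'   values (names) to segment label text; defaults to `"Label <value>"`.
#' @return an object of class `seg_object`: list with `dataset`,
#'   `series_uid`, `series_number`, `sop_instance_uid`, `segments` (data
#'   frame of segment_number, label_value, label_text and colors),
#'   `frames` (data frame of segment_number, slice), `geometry`.
#' @export
labelmap_to_seg <- function(labels, reference, meta, ctx,
                            segment_labels = NULL) {
  stopifnot(inherits(labels, "label_map"), inherits(reference, "mr_series"),
            inherits(ctx, "series_context"))
  values <- labels$label_values
  if (length(values) == 0L)
    stop_input("label map is empty: no nonzero voxels to segment")
  if (!geometry_matches(labels$affine, dim(labels$data),
                        reference$affine, reference$shape))
    stop_geometry("label map grid does not match the reference series ",
                  "(voxel size, spacing and orientation must match within 1e-3)")

  geom <- affine_to_slice_geometry(labels$affine, dim(labels$data))
  data <- labels$data
  n_slices <- dim(data)[3]
  emit_to_src <- if (geom$flip_slices) rev(seq_len(n_slices)) else seq_len(n_slices)

  colors <- assign_segment_colors(length(values))
  cielab <- attr(colors, "cielab")
  texts <- vapply(seq_along(values), function(s) {
    v <- as.character(values[s])
    if (!is.null(segment_labels) && v %in% names(segment_labels))
      segment_labels[[v]] else paste("Label", v)
  }, "")

  segment_items <- lapply(seq_along(values), function(s) {
    dcm_ds(
      SegmentNumber = s,
      SegmentLabel = texts[s],
      SegmentAlgorithmType = "MANUAL",
      RecommendedDisplayCIELabValue = cielab[s, ],
      SegmentedPropertyCategoryCodeSequence = .CODE_TISSUE(),
      SegmentedPropertyTypeCodeSequence = .CODE_TISSUE()
    )
  })

  fragments <- list()
  per_frame <- list()
  frame_rows <- list()
  referenced_k <- integer(0)
  for (s in seq_along(values)) {
    for (k_emit in seq_len(n_slices)) {
      k_src <- emit_to_src[k_emit]
      mask <- data[, , k_src] == values[s]
      if (!any(mask)) next
      frame_bytes <- as.raw(as.integer(as.vector(mask)))
      fragments[[length(fragments) + 1L]] <- rle_encode_frame(frame_bytes)$bytes
      referenced_k <- union(referenced_k, k_emit)
      per_frame[[length(per_frame) + 1L]] <- dcm_ds(
        FrameContentSequence = list(dcm_ds(
          DimensionIndexValues = c(s, k_emit))),
        PlanePositionSequence = list(dcm_ds(
          ImagePositionPatient = geom$positions[k_emit, ])),
        DerivationImageSequence = list(dcm_ds(
          SourceImageSequence = list(dcm_ds(
            ReferencedSOPClassUID = reference$sop_class,
            ReferencedSOPInstanceUID = reference$instance_uids[k_emit],
            PurposeOfReferenceCodeSequence = .CODE_SOURCE_PURPOSE()
          )),
          DerivationCodeSequence = .CODE_SEGMENTATION()
        )),
        SegmentIdentificationSequence = list(dcm_ds(
          ReferencedSegmentNumber = s))
      )
      frame_rows[[length(frame_rows) + 1L]] <-
        data.frame(segment_number = s, slice = k_emit)
    }
  }
  n_frames <- length(fragments)

  dim_org_uid <- new_uid(ctx)
  sop_instance_uid <- new_uid(ctx)
  series_uid <- new_uid(ctx)
  series_number <- next_series_number(ctx)
  clock <- ctx_date_time(ctx)
  seg_desc <- if (is.na(labels$source_path)) "label segmentation"
    else basename(labels$source_path)
  referenced_k <- sort(referenced_k)

  pix <- fragments
  attr(pix, "encapsulated") <- TRUE

  ds <- dcm_ds(
    SOPClassUID = DCM_UID$segmentation_storage,
    SOPInstanceUID = sop_instance_uid,
    StudyInstanceUID = ctx$study_uid,
    SeriesInstanceUID = series_uid,
    FrameOfReferenceUID = ctx$frame_of_reference_uid,
    Modality = "SEG",
    SpecificCharacterSet = "ISO_IR 100",
    ImageType = c("DERIVED", "PRIMARY"),
    SeriesNumber = series_number,
    InstanceNumber = 1L,
    SeriesDescription = seg_desc,
    SeriesDate = clock$date,
    SeriesTime = clock$time,
    ContentDate = clock$date,
    ContentTime = clock$time,
    Manufacturer = "dicomnav",
    ManufacturerModelName = "dicomnav converter",
    SoftwareVersions = .IMPLEMENTATION_VERSION,
    PositionReferenceIndicator = character(0),
    ContentLabel = "SEGMENTATION",
    ContentDescription = seg_desc,
    ContentCreatorName = "dicomnav",
    Rows = unname(geom$shape["rows"]),
    Columns = unname(geom$shape["columns"]),
    NumberOfFrames = n_frames,
    SamplesPerPixel = 1L,
    PhotometricInterpretation = "MONOCHROME2",
    BitsAllocated = 8L,
    BitsStored = 8L,
    HighBit = 7L,
    PixelRepresentation = 0L,
    LossyImageCompression = "00",
    SegmentationType = "BINARY",
    SegmentSequence = segment_items,
    DimensionOrganizationSequence = list(dcm_ds(
      DimensionOrganizationUID = dim_org_uid)),
    DimensionIndexSequence = list(
      dcm_ds(DimensionOrganizationUID = dim_org_uid,
             DimensionIndexPointer = c(0x0062L, 0x000BL),
             FunctionalGroupPointer = c(0x0062L, 0x000AL)),
      dcm_ds(DimensionOrganizationUID = dim_org_uid,
             DimensionIndexPointer = c(0x0020L, 0x0032L),
             FunctionalGroupPointer = c(0x0020L, 0x9113L))
    ),
    SharedFunctionalGroupsSequence = list(dcm_ds(
      PixelMeasuresSequence = list(dcm_ds(
        PixelSpacing = geom$pixel_spacing,
        SliceThickness = geom$slice_spacing,
        SpacingBetweenSlices = geom$slice_spacing)),
      PlaneOrientationSequence = list(dcm_ds(
        ImageOrientationPatient = geom$orientation))
    )),
    PerFrameFunctionalGroupsSequence = per_frame,
    ReferencedSeriesSequence = list(dcm_ds(
      SeriesInstanceUID = reference$series_uid,
      ReferencedInstanceSequence = lapply(referenced_k, function(k) dcm_ds(
        ReferencedSOPClassUID = reference$sop_class,
        ReferencedSOPInstanceUID = reference$instance_uids[k]))
    )),
    PixelData = pix
  )
  ds <- apply_template(ds, meta)

  structure(list(
    dataset = ds,
    transfer_syntax = DCM_UID$rle_lossless,
    series_uid = series_uid,
    series_number = series_number,
    sop_instance_uid = sop_instance_uid,
    reference_series_uid = reference$series_uid,
    segments = data.frame(
      segment_number = seq_along(values),
      label_value = values,
      label_text = texts,
      red = colors[, 1], green = colors[, 2], blue = colors[, 3]
    ),
    frames = do.call(rbind, frame_rows),
    geometry = geom,
    shape = dim(labels$data),
    affine = labels$affine,
    source_path = labels$source_path
  ), class = "seg_object")
}

#' Write a Segmentation object to disk
#'
#' @param seg a `seg_object` from [labelmap_to_seg()].
#' @param outdir output directory.
#' @return the written file path (`<series number>/SEG.1.dcm`).
#' @export
write_seg_object <- function(seg, outdir) {
  stopifnot(inherits(seg, "seg_object"))
  path <- file.path(outdir, seg$series_number, "SEG.1.dcm")
  write_dicom_file(seg$dataset, path, transfer_syntax = seg$transfer_syntax)
  path
}

#' Recompose a label volume from an emitted Segmentation file
#'
#' Validation decoder: reads a SEG file written by this package, decodes
#' every RLE frame, maps each frame back to its slice through the per-frame
#' plane positions, and rebuilds the integer label array on the original
#' voxel grid.  Label values are recovered from the default
#' `"Label <value>"` segment text (falling back to the segment number).
#'
#' @param path path to a SEG DICOM file.
#' @param affine the label map's voxel-to-world affine (defines the target
#'   grid).
#' @param shape the label map's 3D extent.
#' @return integer 3D array of label values on the original grid.
#' @export
seg_to_labelmap <- function(path, affine, shape) {
  dcm <- read_dicom(path)
  geom <- affine_to_slice_geometry(affine, shape)
  n_slices <- shape[3]
  emit_to_src <- if (geom$flip_slices) rev(seq_len(n_slices)) else seq_len(n_slices)

  rows <- dcm_attr(dcm, "Rows")
  cols <- dcm_attr(dcm, "Columns")
  if (rows != geom$shape["rows"] || cols != geom$shape["columns"])
    stop_geometry("SEG frame size does not match the supplied grid")

  segs <- dcm_attr(dcm, "SegmentSequence")
  seg_value <- vapply(segs, function(item) {
    txt <- dcm_attr(item, "SegmentLabel", default = "")
    v <- suppressWarnings(as.integer(sub("^Label ", "", txt)))
    if (is.na(v)) dcm_attr(item, "SegmentNumber") else v
  }, 0L)
  names(seg_value) <- vapply(segs, function(item)
    as.character(dcm_attr(item, "SegmentNumber")), "")

  frames <- dcm_attr(dcm, "PerFrameFunctionalGroupsSequence")
  frags <- dcm_attr(dcm, "PixelData")
  if (length(frames) != length(frags))
    stop_corrupt("SEG frame count does not match fragment count")

  out <- array(0L, dim = shape)
  frame_len <- as.integer(rows) * as.integer(cols)
  for (f in seq_along(frames)) {
    item <- frames[[f]]
    ipp <- dcm_attr(dcm_attr(item, "PlanePositionSequence")[[1]],
                    "ImagePositionPatient")
    d2 <- rowSums((geom$positions - matrix(ipp, nrow(geom$positions), 3,
                                           byrow = TRUE))^2)
    k_emit <- which.min(d2)
    if (d2[k_emit] > 1e-4)
      stop_geometry("SEG frame position matches no slice of the supplied grid")
    seg_num <- dcm_attr(dcm_attr(item, "SegmentIdentificationSequence")[[1]],
                        "ReferencedSegmentNumber")
    value <- seg_value[[as.character(seg_num)]]
    decoded <- rle_decode_frame(frags[[f]], expected_length = frame_len)
    mask <- matrix(as.integer(decoded) != 0L, nrow = dim(out)[1])
    k_src <- emit_to_src[k_emit]
    slice <- out[, , k_src]
    slice[mask] <- value
    out[, , k_src] <- slice
  }
  out
}
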