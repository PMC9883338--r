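# Tractograms become DICOM Surface Segmentation objects: every streamline
# is one Line Sequence polyline primitive over a shared 32-bit point list
# in LPS millimetres.  One object is emitted per tck file, marked as
# deriving from the first structural series of the conversion run.

#' Convert a tractogram to a DICOM Surface Segmentation object
#'
#' The surface point list is the concatenation of all streamline points
#' (RAS input converted to LPS, stored at 32-bit float precision); each
#' streamline becomes one Line Sequence primitive whose 1-based point
#' indices form a contiguous run, so the runs partition the point list in
#' input order.  The object carries the run's frame-of-reference UID, the
#' template attributes, and a derivation reference naming the first
#' structural series of the conversion.
#'
#' @param tracts a non-empty [tractogram()].
#' @param first_series the `mr_series` of the first structural input.
#' @param meta a [load_template()] result.
#' @param ctx a [series_context()].
#' @param color integer RGB triplet (0..255) for recommended display;
#'   defaults to the first palette entry.
#' @param label short text naming the tract object; defaults to the source
#'   file name.
#' @return an object of class `surface_object`: list with `dataset`,
#'   `series_uid`, `series_number`, `sop_instance_uid`, `n_points`,
#'   `runs` (per-streamline index ranges), `reference_series_uid`.
#' @export
tractogram_to_surface <- function(tracts, first_series, meta, ctx,
                                  color = NULL, label = NULL) {
  stopifnot(inherits(tracts, "tractogram"), inherits(first_series, "mr_series"),
            inherits(ctx, "series_context"))
  if (length(tracts$streamlines) == 0L)
    stop_input("empty tractogram: nothing to convert")
  if (is.null(color)) color <- assign_segment_colors(1L)[1, ]
  cielab <- rgb_to_dicom_cielab(matrix(color, 1L))[1, ]
  if (is.null(label)) {
    label <- if (is.na(tracts$source_path)) "tractogram"
      else basename(tracts$source_path)
  }

  lengths <- vapply(tracts$streamlines, nrow, 0L)
  n_points <- sum(lengths)
  pts_ras <- do.call(rbind, tracts$streamlines)
  pts_lps <- ras_to_lps(pts_ras)
  coord_raw <- f32_raw(as.vector(t(pts_lps)))  # x,y,z per point, row-major

  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  line_items <- lapply(seq_along(lengths), function(s) {
    idx <- starts[s]:ends[s]
    dcm_ds(LongPrimitivePointIndexList = raw_from_uint32(idx))
  })

  sop_instance_uid <- new_uid(ctx)
  series_uid <- new_uid(ctx)
  series_number <- next_series_number(ctx)
  clock <- ctx_date_time(ctx)

  ds <- dcm_ds(
    SOPClassUID = DCM_UID$surface_segmentation_storage,
    SOPInstanceUID = sop_instance_uid,
    StudyInstanceUID = ctx$study_uid,
    SeriesInstanceUID = series_uid,
    FrameOfReferenceUID = ctx$frame_of_reference_uid,
    Modality = "SEG",
    SpecificCharacterSet = "ISO_IR 100",
    SeriesNumber = series_number,
    InstanceNumber = 1L,
    SeriesDescription = label,
    SeriesDate = clock$date,
    SeriesTime = clock$time,
    ContentDate = clock$date,
    ContentTime = clock$time,
    Manufacturer = "dicomnav",
    ManufacturerModelName = "dicomnav converter",
    SoftwareVersions = .IMPLEMENTATION_VERSION,
    PositionReferenceIndicator = character(0),
    ContentLabel = "TRACTS",
    ContentDescription = label,
    ContentCreatorName = "dicomnav",
    SegmentSequence = list(dcm_ds(
      SegmentNumber = 1L,
      SegmentLabel = label,
      SegmentAlgorithmType = "AUTOMATIC",
      SegmentAlgorithmName = "streamline tractography",
      RecommendedDisplayCIELabValue = cielab,
      SegmentedPropertyCategoryCodeSequence = .CODE_TISSUE(),
      SegmentedPropertyTypeCodeSequence = .CODE_TISSUE(),
      SurfaceCount = 1L,
      ReferencedSurfaceSequence = list(dcm_ds(
        ReferencedSurfaceNumber = 1L,
        SegmentSurfaceGenerationAlgorithmIdentificationSequence = list(dcm_ds(
          AlgorithmFamilyCodeSequence = list(dcm_ds(
            CodeValue = "123109", CodingSchemeDesignator = "DCM",
            CodeMeaning = "Manual Processing")),
          AlgorithmName = "streamline tractography",
          AlgorithmVersion = .IMPLEMENTATION_VERSION
        )),
        SegmentSurfaceSourceInstanceSequence = list(dcm_ds(
          ReferencedSOPClassUID = first_series$sop_class,
          ReferencedSOPInstanceUID = first_series$instance_uids[1]))
      ))
    )),
    NumberOfSurfaces = 1L,
    SurfaceSequence = list(dcm_ds(
      SurfaceNumber = 1L,
      SurfaceComments = label,
      SurfaceProcessing = "NO",
      RecommendedDisplayCIELabValue = cielab,
      RecommendedPresentationOpacity = 1.0,
      RecommendedPresentationType = "WIREFRAME",
      FiniteVolume = "NO",
      Manifold = "NO",
      SurfacePointsSequence = list(dcm_ds(
        NumberOfSurfacePoints = n_points,
        PointCoordinatesData = coord_raw)),
      SurfacePointsNormalsSequence = list(),
      SurfaceMeshPrimitivesSequence = list(dcm_ds(
        TriangleStripSequence = list(),
        TriangleFanSequence = list(),
        LineSequence = line_items,
        FacetSequence = list()
      ))
    )),
    ReferencedSeriesSequence = list(dcm_ds(
      SeriesInstanceUID = first_series$series_uid,
      ReferencedInstanceSequence = lapply(
        seq_along(first_series$instance_uids), function(k) dcm_ds(
          ReferencedSOPClassUID = first_series$sop_class,
          ReferencedSOPInstanceUID = first_series$instance_uids[k]))
    ))
  )
  ds <- apply_template(ds, meta)

  structure(list(
    dataset = ds,
    transfer_syntax = DCM_UID$explicit_vr_le,
    series_uid = series_uid,
    series_number = series_number,
    sop_instance_uid = sop_instance_uid,
    n_points = n_points,
    runs = data.frame(start = starts, end = ends),
    reference_series_uid = first_series$series_uid,
    source_path = tracts$source_path
  ), class = "surface_object")
}

#' Write a Surface Segmentation object to disk
#'
#' @param surf a `surface_object` from [tractogram_to_surface()].
#' @param outdir output directory.
#' @return the written file path (`<series number>/SEG.1.dcm`).
#' @export
write_surface_object <- function(surf, outdir) {
  stopifnot(inherits(surf, "surface_object"))
  path <- file.path(outdir, surf$series_number, "SEG.1.dcm")
  write_dicom_file(surf$dataset, path, transfer_syntax = surf$transfer_syntax)
  path
}

#' Extract a tractogram from a Surface Segmentation file
#'
#' Inverse of [tractogram_to_surface()] up to 32-bit float precision:
#' reads the surface point list, applies the LPS -> RAS involution, and
#' rebuilds one streamline per Line Sequence primitive in stored order.
#'
#' @param path path to a Surface Segmentation DICOM file (or an already
#'   parsed `dicom_file`).
#' @return a [tractogram()].
#' @export
surface_to_tractogram <- function(path) {
  dcm <- if (inherits(path, "dicom_file")) path else read_dicom(path)
  surfaces <- dcm_attr(dcm, "SurfaceSequence")
  if (is.null(surfaces) || length(surfaces) == 0L)
    stop_corrupt("no SurfaceSequence in ", if (is.character(path)) path else "object")
  surf <- surfaces[[1]]
  pts_item <- dcm_attr(surf, "SurfacePointsSequence")[[1]]
  n_points <- dcm_attr(pts_item, "NumberOfSurfacePoints")
  coord_raw <- dcm_attr(pts_item, "PointCoordinatesData")
  coords <- readBin(coord_raw, "double", n = length(coord_raw) / 4L,
                    size = 4L, endian = "little")
  if (length(coords) < 3 * n_points)
    stop_corrupt("surface point list shorter than declared point count")
  pts_lps <- matrix(coords[seq_len(3 * n_points)], ncol = 3L, byrow = TRUE)

  prim <- dcm_attr(surf, "SurfaceMeshPrimitivesSequence")[[1]]
  lines <- dcm_attr(prim, "LineSequence")
  if (is.null(lines) || length(lines) == 0L)
    stop_corrupt("surface object contains no line primitives")
  streamlines <- lapply(lines, function(item) {
    idx_raw <- dcm_attr(item, "LongPrimitivePointIndexList")
    idx <- readBin(idx_raw, "integer", n = length(idx_raw) / 4L,
                   size = 4L, endian = "little")
    if (any(idx < 1L) || any(idx > n_points))
      stop_corrupt("line primitive point index out of range (indices are 1-based)")
    lps_to_ras(pts_lps[idx, , drop = FALSE])
  })
  tractogram(streamlines,
             source_path = if (is.character(path)) path else NA_character_)
}
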