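# Coordinate conventions.
#
# NIfTI volumes map voxel indices (0-based) to world RAS millimetres through
# a 4x4 affine; DICOM describes the same grid as per-slice plane origins and
# row/column direction cosines in LPS millimetres.  RAS -> LPS negates the
# first two axes.  Index (0,0,0) is the centre of the first voxel in both
# conventions, so no half-voxel shift is involved.

#' Convert RAS coordinates to LPS
#'
#' Negates the first two components (right->left, anterior->posterior); the
#' superior axis is shared.  The map is its own inverse.
#'
#' @param p numeric vector of length 3, or an `n x 3` matrix of points, in
#'   RAS millimetres.
#' @return the same shape in LPS millimetres.
#' @export
ras_to_lps <- function(p) {
  if (!all(is.finite(p))) stop_input("non-finite coordinate in RAS->LPS conversion")
  if (is.matrix(p)) {
    p[, 1:2] <- -p[, 1:2]
    p
  } else {
    stopifnot(length(p) == 3L)
    c(-p[1], -p[2], p[3])
  }
}

#' @rdname ras_to_lps
#' @export
lps_to_ras <- ras_to_lps

.check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop_input("affine must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop_input("affine last row must be (0, 0, 0, 1)")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop_input("affine voxel axes are singular")
  invisible(affine)
}

#' Load a 3D NIfTI image as an image volume
#'
#' Reads a single-component 3D NIfTI-1 image (a trailing singleton fourth
#' dimension is squeezed).  The voxel-to-world affine is taken from the
#' NIfTI sform when set, otherwise the qform.  Genuinely 4D inputs are
#' refused: multiple component images, such as fMRI time series or raw
#' diffusion data, are not supported.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param intent `"structural"` or `"label"`.
#' @return an object of class `image_volume`: list with `data` (3D array),
#'   `affine` (4x4 voxel-index -> RAS mm), `intent`, `source_path`.
#' @export
read_nifti_volume <- function(path, intent = c("structural", "label")) {
  intent <- match.arg(intent)
  if (!file.exists(path)) stop_format("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_format("cannot read NIfTI file ",
                                                  path, ": ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) > 3L) {
    extra <- d[-(1:3)]
    if (any(extra != 1L))
      stop_input("multiple component images, such as fMRI time series or raw ",
                 "diffusion data, are not supported: ", path,
                 " has dimensions ", paste(d, collapse = "x"))
    img_data <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    img_data <- array(as.numeric(img), dim = d)
  } else {
    stop_input("expected a 3D image, got ", length(d), " dimensions: ", path)
  }
  affine <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attr(affine, "code") <- NULL
  .check_affine(affine)
  image_volume(img_data, affine, intent = intent, source_path = path)
}

#' Write an image volume as NIfTI-1
#'
#' Stores the volume's affine in both the sform and qform.
#'
#' @param vol an [image_volume()] (or [label_map()]).
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct an image volume
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-index (0-based) to world RAS mm matrix.
#' @param intent `"structural"` or `"label"`.
#' @param source_path provenance string.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, affine, intent = c("structural", "label"),
                         source_path = NA_character_) {
  intent <- match.arg(intent)
  d <- dim(data)
  if (length(d) == 4L && d[4] == 1L) {
    data <- array(data, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop_input("image volumes must have exactly 3 spatial dimensions")
  .check_affine(affine)
  structure(list(data = data, affine = affine, intent = intent,
                 source_path = source_path),
            class = "image_volume")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Decompose a voxel-to-world affine into DICOM slice geometry
#'
#' Maps a NIfTI-style RAS affine onto the DICOM Image Plane description:
#' row/column direction cosines (LPS, unitless), per-slice plane origins
#' (LPS mm), pixel spacing and slice spacing.  The third voxel axis is the
#' slice axis; no axis permutation is performed.  Sheared grids (voxel axes
#' not orthogonal within `|dot| <= 1e-4` of unit vectors) are refused rather
#' than resampled, since resampling would silently alter data destined for
#' surgery.  Left-handed grids are handled by flipping the slice order
#' (`flip_slices = TRUE`); callers must flip the array accordingly.
#'
#' @param affine 4x4 voxel-index (0-based) to RAS mm matrix.
#' @param shape integer vector of 3 voxel extents (i, j, k).
#' @return a list of class `slice_geometry`: `orientation` (6 direction
#'   cosines, row then column), `positions` (`n_slices x 3` LPS origins),
#'   `pixel_spacing` (row, column, mm), `slice_spacing` (mm), `shape`
#'   (rows, columns, slices), `flip_slices`, `normal`.
#' @export
affine_to_slice_geometry <- function(affine, shape) {
  .check_affine(affine)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  A <- affine[1:3, 1:3]
  spacing <- sqrt(colSums(A^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop_input("affine has zero or negative voxel spacing")
  U <- sweep(A, 2L, spacing, "/")
  dots <- c(abs(sum(U[, 1] * U[, 2])),
            abs(sum(U[, 1] * U[, 3])),
            abs(sum(U[, 2] * U[, 3])))
  if (any(dots > 1e-4))
    stop_geometry("sheared (non-orthogonal) voxel grid: |dot| of unit axes = ",
                  paste(signif(dots, 3), collapse = ", "),
                  "; resampling is never performed")

  flip <- c(-1, -1, 1)
  A_lps <- A * flip            # negate first two rows
  origin_lps <- affine[1:3, 4] * flip
  row_dir <- A_lps[, 1] / spacing[1]
  col_dir <- A_lps[, 2] / spacing[2]
  slice_vec <- A_lps[, 3]
  normal <- .cross3(row_dir, col_dir)
  flip_slices <- sum(normal * slice_vec) < 0

  n_slices <- shape[3]
  k_idx <- if (flip_slices) rev(seq_len(n_slices) - 1L) else seq_len(n_slices) - 1L
  positions <- t(origin_lps + slice_vec %o% as.numeric(k_idx))
  dimnames(positions) <- NULL

  structure(list(
    orientation = c(row_dir, col_dir),
    positions = positions,
    pixel_spacing = c(spacing[2], spacing[1]),  # (row, column) per DICOM
    slice_spacing = spacing[3],
    shape = c(rows = shape[2], columns = shape[1], slices = shape[3]),
    flip_slices = flip_slices,
    normal = normal
  ), class = "slice_geometry")
}

# world LPS position of voxel centre (i, j, k), all 0-based, k in EMITTED
# slice order (i.e. after any left-handed flip)
slice_geometry_position <- function(geom, i, j, k) {
  geom$positions[k + 1L, ] +
    geom$orientation[1:3] * geom$pixel_spacing[2] * i +
    geom$orientation[4:6] * geom$pixel_spacing[1] * j
}

# compare two grids the way the converter matches label maps to structural
# references: shape, spacing and orientation within tol; origins are NOT
# compared (inputs are trusted to be coregistered, never checked)
geometry_matches <- function(affine_a, shape_a, affine_b, shape_b, tol = 1e-3) {
  if (!all(as.integer(shape_a) == as.integer(shape_b))) return(FALSE)
  ga <- affine_to_slice_geometry(affine_a, shape_a)
  gb <- affine_to_slice_geometry(affine_b, shape_b)
  max(abs(ga$orientation - gb$orientation)) <= tol &&
    max(abs(ga$pixel_spacing - gb$pixel_spacing)) <= tol &&
    abs(ga$slice_spacing - gb$slice_spacing) <= tol
}
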