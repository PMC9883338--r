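# Segment display colors.
#
# Up to 30 labels per map, each mapped to a distinct color.  The palette is
# fixed and deterministic across runs and sites: 10 hues stepped around the
# color wheel in three rings of decreasing saturation/value, giving 30
# well-separated RGB colors.  DICOM stores recommended display colors as
# CIELab values scaled to unsigned 16 bits (PCS-style encoding).

.SEGMENT_PALETTE <- local({
  hues <- seq(0, 324, by = 36) / 360
  rings <- list(c(s = 1.00, v = 1.00),
                c(s = 0.45, v = 1.00),
                c(s = 1.00, v = 0.55))
  cols <- unlist(lapply(rings, function(r)
    grDevices::hsv(h = hues, s = r["s"], v = r["v"])))
  t(grDevices::col2rgb(cols))  # 30 x 3 matrix of 0..255 RGB
})

#' Assign distinct display colors to segments
#'
#' Returns the first `n` entries of the package's fixed 30-color palette.
#' The palette is deterministic, identical across runs, and pairwise
#' distinct; label maps support at most 30 labels.
#'
#' @param n number of segments (1..30).
#' @return an `n x 3` integer matrix of RGB values in 0..255, with
#'   attribute `"cielab"` holding the `n x 3` DICOM-scaled CIELab values
#'   (unsigned 16-bit).
#' @export
assign_segment_colors <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1L)
    stop_input("number of segments must be a positive integer")
  if (n > 30L)
    stop_input("too many labels: ", n,
               " requested but label images support at most 30 labels")
  rgb <- .SEGMENT_PALETTE[seq_len(n), , drop = FALSE]
  structure(rgb, cielab = rgb_to_dicom_cielab(rgb))
}

#' Convert RGB colors to DICOM-scaled CIELab
#'
#' sRGB (0..255) -> CIELab via [grDevices::convertColor()], then scaled to
#' the DICOM unsigned 16-bit encoding: L* 0..100 maps to 0..65535, a* and
#' b* -128..127 map to 0..65535 with 0 at 0x8080.
#'
#' @param rgb `n x 3` matrix of RGB values in 0..255.
#' @return `n x 3` integer matrix of DICOM CIELab values.
#' @export
rgb_to_dicom_cielab <- function(rgb) {
  rgb <- matrix(as.numeric(rgb), ncol = 3L)
  lab <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  scaled <- cbind(
    round(pmin(pmax(lab[, 1], 0), 100) / 100 * 65535),
    round((pmin(pmax(lab[, 2], -128), 127) + 128) / 255 * 65535),
    round((pmin(pmax(lab[, 3], -128), 127) + 128) / 255 * 65535)
  )
  storage.mode(scaled) <- "integer"
  scaled
}
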