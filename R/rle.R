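# DICOM RLE Lossless (transfer syntax 1.2.840.10008.1.2.5) frame codec.
#
# A frame starts with a 64-byte header of sixteen little-endian uint32
# values: the number of RLE segments (at most 15) followed by the byte
# offset of each segment from the start of the frame (first segment at 64);
# unused slots are zero.  Each segment is a PackBits-style byte stream per
# Annex G; the whole frame is padded to even length.  This converter always
# writes one 8-bit segment per frame (binary masks, one byte per pixel).

#' Run-length encode one frame
#'
#' Encodes a byte sequence as a single-segment DICOM Annex-G RLE frame:
#' literal runs (control byte 0..127 = length - 1) and replicate runs
#' (control byte 257 - length for run lengths 2..128), preceded by the
#' 64-byte RLE frame header and padded to even length.
#'
#' @param frame raw vector (or integer vector of byte values 0..255);
#'   must be non-empty.
#' @return an object of class `rle_frame`: list with `bytes` (the complete
#'   frame including header), `segment_count`, `decoded_length`.
#' @export
rle_encode_frame <- function(frame) {
  if (is.integer(frame) || is.numeric(frame)) frame <- as.raw(frame)
  if (!is.raw(frame)) stop_input("frame must be a raw vector")
  if (length(frame) == 0L) stop_input("cannot RLE-encode an empty frame")
  payload <- .packbits_encode(frame)
  if (length(payload) %% 2L == 1L) payload <- c(payload, as.raw(0L))
  header <- u32_raw(c(1L, 64L, rep(0L, 14L)))
  structure(list(bytes = c(header, payload),
                 segment_count = 1L,
                 decoded_length = length(frame)),
            class = "rle_frame")
}

#' Decode a DICOM RLE frame
#'
#' Inverse of [rle_encode_frame()]; also decodes any well-formed Annex-G
#' frame with up to 15 segments (segments are concatenated in order).  A
#' trailing pad byte is tolerated.
#'
#' @param encoded an `rle_frame`, or a raw vector holding a complete frame
#'   (64-byte header plus payload).
#' @param expected_length optional decoded byte count per segment; when
#'   given, decoding past or short of it raises a corrupt-frame error.
#' @return raw vector of decoded bytes.
#' @export
rle_decode_frame <- function(encoded, expected_length = NULL) {
  bytes <- if (inherits(encoded, "rle_frame")) encoded$bytes else encoded
  if (inherits(encoded, "rle_frame") && is.null(expected_length))
    expected_length <- encoded$decoded_length
  if (!is.raw(bytes)) stop_input("encoded frame must be a raw vector")
  if (length(bytes) < 64L)
    stop_corrupt("RLE frame shorter than its 64-byte header")
  hdr <- readBin(bytes[1:64], "integer", n = 16L, size = 4L, endian = "little")
  n_seg <- hdr[1]
  if (n_seg < 1L || n_seg > 15L)
    stop_corrupt("RLE frame declares ", n_seg, " segments (must be 1..15)")
  offsets <- hdr[2:(1L + n_seg)]
  if (any(offsets < 64L) || any(offsets > length(bytes)))
    stop_corrupt("RLE segment offset outside frame")
  ends <- c(offsets[-1], length(bytes))
  out <- raw(0)
  for (s in seq_len(n_seg)) {
    seg <- bytes[(offsets[s] + 1L):ends[s]]
    dec <- tryCatch(
      .packbits_decode(seg, if (is.null(expected_length)) 0L
                       else as.integer(expected_length)),
      error = function(e) stop_corrupt(conditionMessage(e))
    )
    out <- c(out, dec)
  }
  out
}
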