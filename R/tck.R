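# MRtrix .tck streamline file I/O.
#
# A tck file is a text header of "key: value" lines opened by the magic line
# "mrtrix tracks" and closed by "END", followed (at the byte offset named by
# the header's `file` entry) by raw binary coordinate triplets in scanner
# RAS millimetres.  A NaN triplet ends a streamline; an Inf triplet ends the
# stream.

.TCK_MAGIC <- "mrtrix tracks"
.TCK_DATATYPES <- c("Float32LE", "Float32BE", "Float64LE", "Float64BE")

#' Construct a tractogram
#'
#' A tractogram is an ordered collection of streamlines (each an `n x 3`
#' matrix of scanner-space RAS coordinates in millimetres) together with the
#' key/value metadata of its tck header.
#'
#' @param streamlines list of numeric matrices with 3 columns and at least
#'   one row; all coordinates must be finite.
#' @param header named character vector of tck header entries (optional).
#' @param source_path provenance string (optional).
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(streamlines = list(), header = character(),
                       source_path = NA_character_) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (is.null(dim(s)) || ncol(s) != 3L)
      stop_input("each streamline must be an n x 3 coordinate matrix")
    if (nrow(s) < 1L)
      stop_input("streamlines must contain at least one point")
    if (!all(is.finite(s)))
      stop_input("streamline coordinates must be finite (no NaN/Inf)")
    storage.mode(s) <- "double"
    dimnames(s) <- NULL
    s
  })
  structure(list(streamlines = streamlines,
                 header = header,
                 source_path = source_path),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  npts <- sum(vapply(x$streamlines, nrow, 0L))
  cat(sprintf("tractogram: %d streamlines, %d points (RAS mm)\n",
              length(x$streamlines), npts))
  invisible(x)
}

.raw_find <- function(haystack, needle, limit = length(haystack)) {
  nh <- min(length(haystack), limit)
  nn <- length(needle)
  if (nn > nh) return(-1L)
  starts <- which(haystack[seq_len(nh - nn + 1L)] == needle[1])
  for (i in starts)
    if (identical(haystack[i:(i + nn - 1L)], needle)) return(i)
  -1L
}

.parse_tck_header <- function(bytes, path) {
  # header is ASCII up to an END line; locate it on the raw bytes so the
  # binary section (which may contain NULs) is never decoded as text
  end_at <- .raw_find(bytes, charToRaw("\nEND"), limit = 65536L)
  if (end_at < 0L) stop_format("tck header not terminated by END: ", path)
  nl_after <- end_at + 4L
  while (nl_after <= length(bytes) && bytes[nl_after] != as.raw(10L))
    nl_after <- nl_after + 1L
  header_txt <- rawToChar(bytes[seq_len(min(nl_after, length(bytes)))])
  lines <- strsplit(header_txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[lines != ""]
  if (length(lines) < 1L || trimws(lines[1]) != .TCK_MAGIC)
    stop_format("not an MRtrix tck file (missing '", .TCK_MAGIC,
                "' magic line): ", path)
  body <- lines[-1]
  body <- body[toupper(trimws(body)) != "END"]
  keys <- sub(":.*$", "", body)
  vals <- trimws(sub("^[^:]*:", "", body))
  names(vals) <- trimws(keys)
  vals
}

#' Read an MRtrix tck streamline file
#'
#' @param path path to a `.tck` file.
#' @param strict when `TRUE` (default) a mismatch between the header `count`
#'   entry and the number of streamlines read is an error; when `FALSE` it
#'   is downgraded to a warning.  Silent truncation is the dangerous failure
#'   mode for data destined for surgery, so the default refuses.
#' @return a [tractogram()] with streamlines in file order; NaN delimiter
#'   and Inf terminator triplets are consumed and never appear in the point
#'   data.  Coordinates are returned unmodified (scanner RAS millimetres).
#' @export
read_tck <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  bytes <- readBin(path, raw(), file.info(path)$size)
  header <- .parse_tck_header(bytes, path)
  datatype <- header[["datatype"]]
  if (is.null(datatype) || is.na(datatype))
    stop_format("tck header lacks a datatype entry: ", path)
  if (!datatype %in% .TCK_DATATYPES)
    stop_format("unsupported tck datatype '", datatype, "' in ", path,
                "; supported: ", paste(.TCK_DATATYPES, collapse = ", "))
  file_entry <- header[["file"]]
  if (is.null(file_entry) || is.na(file_entry))
    stop_format("tck header lacks a file entry: ", path)
  offset <- suppressWarnings(as.integer(sub("^\\.\\s*", "", file_entry)))
  if (is.na(offset) || offset < 1L)
    stop_format("invalid tck file offset entry '", file_entry, "': ", path)

  size <- if (grepl("^Float32", datatype)) 4L else 8L
  endian <- if (grepl("BE$", datatype)) "big" else "little"
  if (offset + 3L * size > length(bytes))
    stop_corrupt("tck binary section truncated before Inf terminator: ", path)
  payload <- bytes[(offset + 1L):length(bytes)]
  n_vals <- length(payload) %/% size
  vals <- readBin(payload, "double", n = n_vals, size = size, endian = endian)
  n_trip <- length(vals) %/% 3L
  if (n_trip < 1L)
    stop_corrupt("tck binary section truncated before Inf terminator: ", path)
  coords <- matrix(vals[seq_len(n_trip * 3L)], ncol = 3L, byrow = TRUE)

  inf_rows <- which(rowSums(is.infinite(coords)) == 3L)
  if (length(inf_rows) == 0L)
    stop_corrupt("tck binary section truncated before Inf terminator: ", path)
  end_row <- inf_rows[1]
  nan_count <- rowSums(is.nan(coords[seq_len(end_row), , drop = FALSE]))
  if (any(nan_count > 0L & nan_count < 3L))
    stop_corrupt("partial NaN triplet in tck binary section: ", path)

  streamlines <- list()
  start <- 1L
  for (r in seq_len(end_row)) {
    if (nan_count[r] == 3L || r == end_row) {
      if (r > start) {
        streamlines[[length(streamlines) + 1L]] <-
          coords[start:(r - 1L), , drop = FALSE]
      }
      start <- r + 1L
    }
  }
  if (any(!is.finite(unlist(streamlines))))
    stop_corrupt("non-finite coordinate inside a streamline: ", path)

  declared <- suppressWarnings(as.integer(header[["count"]]))
  if (!is.na(declared) && declared != length(streamlines)) {
    msg <- sprintf(
      "tck count mismatch in %s: header declares %d streamlines, file holds %d",
      path, declared, length(streamlines))
    if (strict) stop_corrupt(msg) else warning(msg, call. = FALSE)
  }
  tractogram(streamlines, header = header, source_path = path)
}

#' Write an MRtrix tck streamline file
#'
#' Emits Float32LE binary (the native MRtrix precision) with one NaN triplet
#' after every streamline and a final Inf triplet.  Header keys of the input
#' tractogram are preserved verbatim; `datatype`, `count` and `file` are
#' rewritten to describe the emitted file.
#'
#' @param tract a [tractogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tract, path) {
  stopifnot(inherits(tract, "tractogram"))
  for (s in tract$streamlines)
    if (!all(is.finite(s)))
      stop_input("cannot write non-finite streamline coordinates")

  header <- tract$header
  header <- header[!names(header) %in% c("datatype", "count", "file")]
  lines <- c(.TCK_MAGIC,
             if (length(header)) paste0(names(header), ": ", header),
             "datatype: Float32LE",
             paste0("count: ", length(tract$streamlines)))
  # the `file` entry names the byte offset of the binary section, which
  # depends on the header length; iterate to a fixed point
  offset <- 0L
  repeat {
    hdr <- paste0(paste(c(lines, paste0("file: . ", offset), "END"),
                        collapse = "\n"), "\n")
    if (nchar(hdr, type = "bytes") == offset) break
    offset <- nchar(hdr, type = "bytes")
  }

  vals <- unlist(lapply(tract$streamlines, function(s) {
    c(as.vector(t(s)), rep(NaN, 3))
  }))
  vals <- c(vals, rep(Inf, 3))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeBin(vals, con, size = 4L, endian = "little")
  invisible(path)
}
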