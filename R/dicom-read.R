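# Minimal DICOM Part-10 reader: Explicit VR Little Endian datasets (the
# only encoding this package emits), including defined- and undefined-length
# sequences and encapsulated pixel data fragments.  Used to load template
# files and to validate / round-trip the package's own output.

.read_state <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes
  env$pos <- 1L
  env
}

.take <- function(st, n) {
  if (st$pos + n - 1L > length(st$bytes))
    stop_format("truncated DICOM stream")
  out <- st$bytes[st$pos:(st$pos + n - 1L)]
  st$pos <- st$pos + n
  out
}

.peek_u16 <- function(st, offset = 0L) {
  i <- st$pos + offset
  if (i + 1L > length(st$bytes)) return(NA_integer_)
  as.integer(st$bytes[i]) + 256L * as.integer(st$bytes[i + 1L])
}

.read_u16 <- function(st) {
  b <- .take(st, 2L)
  as.integer(b[1]) + 256L * as.integer(b[2])
}

.read_u32 <- function(st) {
  b <- .take(st, 4L)
  sum(as.double(b) * c(1, 256, 65536, 16777216))
}

.decode_string <- function(b, vr) {
  if (length(b) == 0L) return(character(0))
  s <- rawToChar(b[b != as.raw(0L)])
  s <- sub("[ ]+$", "", s)
  parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
  if (length(parts) == 0L) character(0) else parts
}

.decode_value <- function(vr, b) {
  if (vr %in% .VR_STRING) {
    v <- .decode_string(b, vr)
    if (vr == "DS") v <- as.numeric(v)
    if (vr == "IS") v <- as.integer(v)
    return(v)
  }
  switch(vr,
    US = readBin(b, "integer", n = length(b) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    SS = readBin(b, "integer", n = length(b) / 2L, size = 2L,
                 signed = TRUE, endian = "little"),
    UL = {
      v <- readBin(b, "integer", n = length(b) / 4L, size = 4L,
                   endian = "little")
      v <- as.double(v); v[v < 0] <- v[v < 0] + 4294967296; v
    },
    SL = readBin(b, "integer", n = length(b) / 4L, size = 4L,
                 endian = "little"),
    FL = readBin(b, "double", n = length(b) / 4L, size = 4L,
                 endian = "little"),
    FD = readBin(b, "double", n = length(b) / 8L, size = 8L,
                 endian = "little"),
    AT = readBin(b, "integer", n = length(b) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    b  # OB/OW/OF/OL/UN and anything else: raw
  )
}

# parse one dataset; stops at end_pos (exclusive) or on an item/sequence
# delimiter when delimited = TRUE
.parse_dataset <- function(st, end_pos = NULL, delimited = FALSE) {
  out <- list()
  repeat {
    if (!is.null(end_pos) && st$pos >= end_pos) break
    if (st$pos > length(st$bytes)) break
    if (st$pos + 7L > length(st$bytes)) {
      if (delimited) stop_format("truncated sequence item")
      break
    }
    group <- .read_u16(st)
    element <- .read_u16(st)
    if (group == 0xFFFEL && element %in% c(0xE00DL, 0xE0DDL)) {
      .read_u32(st)  # zero length
      if (!delimited) stop_format("unexpected delimiter item")
      break
    }
    vr <- rawToChar(.take(st, 2L))
    if (!grepl("^[A-Z]{2}$", vr))
      stop_format("not an Explicit VR Little Endian dataset (found VR bytes ",
                  deparse(vr), "); only Explicit VR LE DICOM is supported")
    if (vr %in% .VR_LONG) {
      .take(st, 2L)
      len <- .read_u32(st)
    } else {
      len <- .read_u16(st)
    }
    key <- dcm_tag_key(group, element)
    if (vr == "SQ") {
      items <- list()
      if (len == 4294967295) {
        repeat {
          g <- .read_u16(st); e <- .read_u16(st); l <- .read_u32(st)
          if (g == 0xFFFEL && e == 0xE0DDL) break
          if (!(g == 0xFFFEL && e == 0xE000L)) stop_format("malformed sequence")
          if (l == 4294967295) {
            items[[length(items) + 1L]] <- .parse_dataset(st, delimited = TRUE)
          } else {
            items[[length(items) + 1L]] <- .parse_dataset(st, end_pos = st$pos + l)
          }
        }
      } else {
        seq_end <- st$pos + len
        while (st$pos < seq_end) {
          g <- .read_u16(st); e <- .read_u16(st); l <- .read_u32(st)
          if (!(g == 0xFFFEL && e == 0xE000L)) stop_format("malformed sequence")
          items[[length(items) + 1L]] <- .parse_dataset(st, end_pos = st$pos + l)
        }
      }
      out[[key]] <- list(vr = "SQ", value = items)
    } else if (group == 0x7FE0L && element == 0x0010L && len == 4294967295) {
      # encapsulated pixel data: basic offset table, then one item per frame
      frags <- list()
      first <- TRUE
      repeat {
        g <- .read_u16(st); e <- .read_u16(st); l <- .read_u32(st)
        if (g == 0xFFFEL && e == 0xE0DDL) break
        if (!(g == 0xFFFEL && e == 0xE000L)) stop_format("malformed fragments")
        b <- if (l > 0) .take(st, l) else raw(0)
        if (!first) frags[[length(frags) + 1L]] <- b
        first <- FALSE
      }
      out[[key]] <- list(vr = vr, value = frags, encapsulated = TRUE)
    } else {
      b <- if (len > 0) .take(st, len) else raw(0)
      out[[key]] <- list(vr = vr, value = .decode_value(vr, b))
    }
  }
  out
}

#' Read a DICOM Part-10 file
#'
#' Parses a DICOM Part-10 file written in Explicit VR Little Endian (the
#' encoding this package emits, optionally with RLE-encapsulated pixel
#' data).  Returns the file-meta group and the dataset as flat lists keyed
#' by `GGGGEEEE` hex tags; use [dcm_attr()] to retrieve attributes by
#' DICOM keyword.
#'
#' @param path path to a DICOM file.
#' @return a list with components `meta` (file meta group), `dataset`
#'   (main dataset) and `transfer_syntax` (UID string).
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  n <- file.info(path)$size
  if (is.na(n) || n < 140) stop_format("not a DICOM Part-10 file: ", path)
  bytes <- readBin(path, raw(), n)
  if (!identical(rawToChar(bytes[129:132]), "DICM"))
    stop_format("not a DICOM Part-10 file (missing DICM marker): ", path)
  st <- .read_state(bytes)
  st$pos <- 133L
  # file meta group is always Explicit VR LE
  meta <- list()
  while (.peek_u16(st) == 0x0002L) {
    sub <- .parse_dataset(st, end_pos = st$pos + 8L)  # parse exactly one element
    # .parse_dataset with a tight end_pos reads one full element even if its
    # value extends beyond end_pos, because lengths are honoured during .take
    meta <- c(meta, sub)
  }
  ts <- meta[[dcm_tag_key(0x0002L, 0x0010L)]]$value
  if (is.null(ts)) stop_format("file meta lacks a transfer syntax UID")
  if (!ts %in% c(DCM_UID$explicit_vr_le, DCM_UID$rle_lossless))
    stop_format("unsupported transfer syntax ", ts,
                "; only Explicit VR Little Endian and RLE Lossless are supported")
  ds <- .parse_dataset(st)
  structure(list(meta = meta, dataset = ds, transfer_syntax = ts),
            class = "dicom_file")
}

#' Get a DICOM attribute by keyword
#'
#' @param x a `dicom_file` from [read_dicom()], or a dataset / sequence-item
#'   list from one.
#' @param keyword DICOM attribute keyword, e.g. `"PatientID"`.
#' @param default value returned when the attribute is absent.
#' @return the decoded attribute value (character, numeric, raw, or a list
#'   of sequence items for SQ attributes).
#' @export
dcm_attr <- function(x, keyword, default = NULL) {
  ds <- if (inherits(x, "dicom_file")) x$dataset else x
  entry <- dcm_tag_lookup(keyword)
  el <- ds[[dcm_tag_key(entry$group, entry$element)]]
  if (is.null(el)) default else el$value
}

dcm_has <- function(x, keyword) {
  ds <- if (inherits(x, "dicom_file")) x$dataset else x
  entry <- dcm_tag_lookup(keyword)
  !is.null(ds[[dcm_tag_key(entry$group, entry$element)]])
}
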