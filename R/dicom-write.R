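# Minimal DICOM Part-10 writer: Explicit VR Little Endian datasets, defined
# length sequences, and encapsulated (RLE) pixel data.  Only the attribute
# set in the package dictionary is supported; this is an emitter for the
# objects this converter produces, not a general DICOM toolkit.

.VR_LONG <- c("OB", "OD", "OF", "OL", "OW", "SQ", "UC", "UR", "UT", "UN")
.VR_STRING <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                "PN", "SH", "ST", "TM", "UC", "UR", "UT", "UI")

# little-endian byte packers ------------------------------------------------

u16_raw <- function(x) {
  x <- as.integer(x)
  x[x > 32767L] <- x[x > 32767L] - 65536L
  writeBin(x, raw(), size = 2L, endian = "little")
}

u32_raw <- function(x) {
  x <- as.double(x)
  x[x > 2147483647] <- x[x > 2147483647] - 4294967296
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

f32_raw <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "little")
f64_raw <- function(x) writeBin(as.numeric(x), raw(), size = 8L, endian = "little")

#' @noRd
raw_from_uint16 <- function(v) {
  v <- as.integer(round(v))
  if (any(v < 0L | v > 65535L)) stop("value outside unsigned 16-bit range")
  u16_raw(v)
}

raw_from_uint32 <- function(v) u32_raw(v)

# decimal-string formatting (DS, max 16 chars per value)
fmt_ds <- function(x) {
  if (is.character(x)) return(x)
  s <- vapply(x, function(v) {
    out <- formatC(v, format = "g", digits = 10, width = 1)
    out <- gsub(" ", "", out)
    if (nchar(out) > 16) out <- formatC(v, format = "g", digits = 8, width = 1)
    out
  }, "")
  s
}

# element constructor -------------------------------------------------------

dcm_el <- function(keyword, value, vr = NULL) {
  entry <- dcm_tag_lookup(keyword)
  if (is.null(vr)) vr <- entry$vr
  structure(
    list(group = entry$group, element = entry$element, vr = vr,
         keyword = keyword, value = value),
    class = "dcm_element"
  )
}

# Build a dataset (ordered element list) from keyword = value pairs.
# SQ values: list of datasets (each itself a list of dcm_element).
# Raw values are passed through for OB/OW/OF/OL.
dcm_ds <- function(...) {
  args <- list(...)
  stopifnot(length(args) == 0L || !is.null(names(args)))
  els <- lapply(names(args), function(nm) dcm_el(nm, args[[nm]]))
  els
}

ds_add <- function(ds, ...) c(ds, dcm_ds(...))

# value -> raw encoding ------------------------------------------------------

encode_value <- function(vr, value) {
  if (is.null(value) || length(value) == 0L) return(raw(0))
  if (vr %in% c("OB", "OW", "OF", "OL", "OD", "UN")) {
    stopifnot(is.raw(value))
    if (length(value) %% 2L == 1L) value <- c(value, as.raw(0L))
    return(value)
  }
  if (vr %in% .VR_STRING) {
    if (vr == "DS") value <- fmt_ds(value)
    if (vr == "IS") value <- as.character(as.integer(value))
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L)
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    return(b)
  }
  switch(vr,
    US = u16_raw(value),
    SS = u16_raw(value),
    UL = u32_raw(value),
    SL = u32_raw(value),
    FL = f32_raw(value),
    FD = f64_raw(value),
    AT = u16_raw(value),  # pairs of (group, element)
    stop("unsupported VR for encoding: ", vr)
  )
}

encode_element <- function(el) {
  if (el$vr == "SQ") {
    items <- lapply(el$value, function(item_ds) {
      content <- encode_dataset(item_ds, sort = TRUE)
      c(u16_raw(c(0xFFFEL, 0xE000L)), u32_raw(length(content)), content)
    })
    body <- if (length(items)) do.call(c, items) else raw(0)
    return(c(u16_raw(c(el$group, el$element)), charToRaw("SQ"), raw(2L),
             u32_raw(length(body)), body))
  }
  if (identical(attr(el$value, "encapsulated"), TRUE)) {
    # encapsulated pixel data: undefined length, empty BOT, one item/frame
    frags <- lapply(el$value, function(fr) {
      if (length(fr) %% 2L == 1L) fr <- c(fr, as.raw(0L))
      c(u16_raw(c(0xFFFEL, 0xE000L)), u32_raw(length(fr)), fr)
    })
    body <- c(
      u16_raw(c(0xFFFEL, 0xE000L)), u32_raw(0L),       # empty basic offset table
      do.call(c, frags),
      u16_raw(c(0xFFFEL, 0xE0DDL)), u32_raw(0L)        # sequence delimiter
    )
    return(c(u16_raw(c(el$group, el$element)), charToRaw("OB"), raw(2L),
             as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)), body))
  }
  body <- encode_value(el$vr, el$value)
  hdr <- c(u16_raw(c(el$group, el$element)), charToRaw(el$vr))
  if (el$vr %in% .VR_LONG) {
    c(hdr, raw(2L), u32_raw(length(body)), body)
  } else {
    if (length(body) > 65534L)
      stop("value too long for short-form VR ", el$vr)
    c(hdr, u16_raw(length(body)), body)
  }
}

encode_dataset <- function(ds, sort = TRUE) {
  if (length(ds) == 0L) return(raw(0))
  if (sort) {
    ord <- order(vapply(ds, function(e) e$group * 2^16 + e$element, 0))
    ds <- ds[ord]
  }
  do.call(c, lapply(ds, encode_element))
}

# Part-10 file --------------------------------------------------------------

.IMPLEMENTATION_CLASS_UID <- "2.25.848269350131973566612992941537281264"
.IMPLEMENTATION_VERSION <- "dicomnav-0.1"

dcm_find <- function(ds, keyword) {
  entry <- dcm_tag_lookup(keyword)
  for (el in ds)
    if (el$group == entry$group && el$element == entry$element) return(el)
  NULL
}

write_dicom_file <- function(ds, path, transfer_syntax = DCM_UID$explicit_vr_le) {
  sop_class <- dcm_find(ds, "SOPClassUID")
  sop_inst <- dcm_find(ds, "SOPInstanceUID")
  if (is.null(sop_class) || is.null(sop_inst))
    stop("dataset must carry SOPClassUID and SOPInstanceUID")
  meta <- dcm_ds(
    FileMetaInformationVersion = as.raw(c(0L, 1L)),
    MediaStorageSOPClassUID = sop_class$value,
    MediaStorageSOPInstanceUID = sop_inst$value,
    TransferSyntaxUID = transfer_syntax,
    ImplementationClassUID = .IMPLEMENTATION_CLASS_UID,
    ImplementationVersionName = .IMPLEMENTATION_VERSION
  )
  meta_bytes <- encode_dataset(meta, sort = TRUE)
  group_len <- encode_element(dcm_el("FileMetaInformationGroupLength",
                                     length(meta_bytes)))
  body <- encode_dataset(ds, sort = TRUE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(group_len, con)
  writeBin(meta_bytes, con)
  writeBin(body, con)
  invisible(path)
}
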