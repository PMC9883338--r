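# Template DICOM handling: a file from the session being analysed supplies
# the patient and institutional attributes copied onto every converted
# object.  The whitelist is explicit and closed: nothing else (in
# particular no pixel data and no series/instance UIDs) is ever propagated,
# so acquisition parameters can never misdescribe derived images.

.TEMPLATE_WHITELIST <- c(
  "PatientName", "PatientID", "PatientBirthDate", "PatientSex",
  "StudyDate", "StudyTime", "StudyDescription", "AccessionNumber",
  "InstitutionName", "ReferringPhysicianName", "StudyID",
  "StudyInstanceUID"
)

#' Load patient/institution attributes from a template DICOM file
#'
#' Copies a closed whitelist of patient-, study- and institution-level
#' attributes from an existing DICOM file (typically one from the imaging
#' session being converted).  Absent optional attributes are simply
#' omitted.  Pixel data and series/instance-level UIDs are never copied.
#'
#' @param path path to a DICOM Part-10 file.
#' @return an object of class `template_metadata`: a named list of
#'   attribute values.
#' @export
load_template <- function(path) {
  dcm <- read_dicom(path)
  attrs <- list()
  for (kw in .TEMPLATE_WHITELIST) {
    v <- dcm_attr(dcm, kw)
    if (!is.null(v) && length(v) > 0L && !identical(v, ""))
      attrs[[kw]] <- v
  }
  structure(list(attributes = attrs, source_path = path),
            class = "template_metadata")
}

# append whitelisted template attributes (minus the study UID, which the
# series context owns) to a dataset under construction
apply_template <- function(ds, meta) {
  stopifnot(inherits(meta, "template_metadata"))
  for (kw in setdiff(names(meta$attributes), "StudyInstanceUID"))
    ds <- c(ds, list(dcm_el(kw, meta$attributes[[kw]])))
  # Type 2 patient attributes must exist even when the template lacks them
  for (kw in c("PatientName", "PatientID", "PatientBirthDate", "PatientSex",
               "ReferringPhysicianName", "AccessionNumber", "StudyID",
               "StudyDate", "StudyTime"))
    if (!kw %in% names(meta$attributes))
      ds <- c(ds, list(dcm_el(kw, character(0))))
  ds
}
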