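Package: dicomnav
Title: Convert NIfTI Volumes, Label Maps and MRtrix Tractography to DICOM for Surgical Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts a coregistered neurosurgical imaging workup produced by
    research neuroimaging software into a standards-conformant DICOM dataset
    ready for import into commercial surgical-navigation suites. Structural
    NIfTI volumes become classic single-frame MR-modality series, integer
    label maps become DICOM Segmentation objects with run-length-encoded
    binary frames and one distinctly colored segment per label (up to 30),
    and MRtrix '.tck' streamline files become Surface Segmentation objects
    carrying each streamline as a Line Sequence polyline primitive. All
    emitted objects share a single frame of reference and carry patient and
    institutional attributes copied from a template DICOM file; no
    resampling or coregistration is ever performed. Includes a deterministic
    synthetic-fixture generator and a command-line entry point,
    'importTractography'.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    grDevices,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
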