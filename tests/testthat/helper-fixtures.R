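# Shared test helpers: the independent pydicom/nibabel oracle, random
# orthogonal affines, and a ready-made template/context pair.

oracle_script <- function() {
  p <- system.file("python", "oracle.py", package = "dicomnav")
  stopifnot(nzchar(p))
  p
}

# run the independent Python reader (pydicom / nibabel) and parse its JSON
oracle <- function(...) {
  out <- suppressWarnings(
    system2("python", c(oracle_script(), ...), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("oracle failed: ", paste(out, collapse = "\n"))
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = TRUE)
}

# random rigid-ish affine: rotation x positive scaling + translation,
# optionally left-handed (negated third axis)
rand_orthogonal_affine <- function(seed, left_handed = FALSE,
                                   scale_range = c(0.5, 3)) {
  set.seed(seed)
  th <- stats::runif(3, -1, 1)
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])),
              c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0),
              c(0, 0, 1))
  S <- diag(stats::runif(3, scale_range[1], scale_range[2]))
  if (left_handed) S[3, 3] <- -S[3, 3]
  A <- Rx %*% Ry %*% Rz %*% S
  rbind(cbind(A, stats::runif(3, -50, 50)), c(0, 0, 0, 1))
}

# template + metadata + context ready for writer calls
make_test_setup <- function(seed = 20260920L, dir = withr::local_tempdir()) {
  tpl <- file.path(dir, "template.dcm")
  make_minimal_template_dicom(list(
    PatientID = "TEST01", PatientName = "Test^Subject",
    PatientBirthDate = "20100101", PatientSex = "O",
    StudyDate = "20260101", StudyTime = "090000",
    StudyDescription = "synthetic study",
    InstitutionName = "Test Institute"
  ), tpl, ctx = series_context(rng_seed = seed))
  ctx <- series_context(rng_seed = seed + 1L, fixed_clock = "20260101090000")
  meta <- load_template(tpl)
  ctx$study_uid <- meta$attributes$StudyInstanceUID
  list(template_path = tpl, meta = meta, ctx = ctx)
}

# normalise the oracle's polyline index runs: jsonlite simplifies a list of
# equal-length runs to a matrix
as_runs <- function(runs) {
  if (is.matrix(runs)) runs <- lapply(seq_len(nrow(runs)), function(i) runs[i, ])
  lapply(runs, as.integer)
}

# world position of 0-based voxel (i,j,k) through the affine path, in LPS
affine_voxel_lps <- function(affine, i, j, k) {
  ras_to_lps((affine %*% c(i, j, k, 1))[1:3])
}
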