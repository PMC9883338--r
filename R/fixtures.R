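# Synthetic input generators: phantom volumes, disjoint label blobs,
# helical tractograms and a minimal template DICOM.  Everything is
# deterministic under its seed, so every module and the end-to-end pipeline
# are testable without downloads or stored binaries.

#' Specify a phantom volume
#'
#' @param shape integer vector of 3 positive voxel extents.
#' @param affine 4x4 voxel-to-RAS-mm matrix; defaults to identity spacing.
#' @param seed integer seed (used by `"noise"` content).
#' @param content `"sphere"` (filled ball at the grid centre),
#'   `"gradient"` (value `i + 2*j + 3*k` at 0-based voxel `(i,j,k)`), or
#'   `"noise"` (seeded standard normal).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L), affine = NULL,
                         seed = 1L, content = c("sphere", "gradient", "noise")) {
  content <- match.arg(content)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop_input("phantom shape must be 3 positive integers")
  if (is.null(affine)) affine <- diag(4)
  .check_affine(affine)
  structure(list(shape = shape, affine = affine, seed = as.integer(seed),
                 content = content),
            class = "phantom_spec")
}

#' Generate a phantom image volume
#'
#' Deterministic given the spec.  Sphere content places a filled ball of
#' radius `min(shape)/4` voxels (value 100, background 0) at the grid
#' centre `(shape - 1)/2`, inclusive of boundary voxels
#' (`distance^2 <= radius^2`).
#'
#' @param spec a [phantom_spec()].
#' @param radius sphere radius in voxels (sphere content only).
#' @return an [image_volume()].
#' @export
make_phantom_volume <- function(spec, radius = min(spec$shape) / 4) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  i <- (seq_len(d[1]) - 1)
  j <- (seq_len(d[2]) - 1)
  k <- (seq_len(d[3]) - 1)
  data <- switch(spec$content,
    sphere = {
      centre <- (d - 1) / 2
      di2 <- (i - centre[1])^2
      dj2 <- (j - centre[2])^2
      dk2 <- (k - centre[3])^2
      dist2 <- outer(outer(di2, dj2, "+"), dk2, "+")
      array(ifelse(dist2 <= radius^2, 100, 0), dim = d)
    },
    gradient = {
      array(outer(outer(i, 2 * j, "+"), 3 * k, "+"), dim = d)
    },
    noise = {
      withr_seed <- spec$seed
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
              else suppressWarnings(rm(".Random.seed", envir = globalenv())))
      set.seed(withr_seed)
      array(stats::rnorm(prod(d)), dim = d)
    })
  image_volume(data, spec$affine, intent = "structural")
}

#' Generate a label map of disjoint blobs
#'
#' Places `n_labels` small spheres with distinct integer values on a 3D
#' lattice of non-overlapping cells, so blob supports are pairwise
#' disjoint.  With `over_limit = TRUE` the 1..30 bound is not enforced,
#' producing deliberately invalid input that exercises the too-many-labels
#' error path downstream.
#'
#' @param n_labels number of distinct nonzero values (1..30 unless
#'   `over_limit`).
#' @param spec a [phantom_spec()] supplying shape and affine.
#' @param values integer label values to use (default `1:n_labels`).
#' @param over_limit allow more than 30 labels (error-path fixture).
#' @return a [label_map()] (a plain `image_volume` when `over_limit`).
#' @export
make_label_blobs <- function(n_labels, spec, values = seq_len(n_labels),
                             over_limit = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_labels <- as.integer(n_labels)
  if (n_labels < 1L) stop_input("n_labels must be >= 1")
  if (!over_limit && n_labels > 30L)
    stop_input("n_labels must be <= 30 (use over_limit = TRUE for the ",
               "error-path fixture)")
  stopifnot(length(values) == n_labels)
  d <- spec$shape
  m <- ceiling(n_labels^(1 / 3) - 1e-9)
  cell <- d / m
  r <- max(1, floor(min(cell) / 3))
  if (min(cell) < 2)
    stop_input("grid too small to fit ", n_labels, " disjoint blobs")
  data <- array(0, dim = d)
  coords <- as.matrix(expand.grid(ci = seq_len(m), cj = seq_len(m),
                                  ck = seq_len(m)))
  for (b in seq_len(n_labels)) {
    centre <- (coords[b, ] - 0.5) * cell + 0.5  # 1-based continuous coords
    lo <- pmax(1, floor(centre - r))
    hi <- pmin(d, ceiling(centre + r))
    for (kk in lo[3]:hi[3]) for (jj in lo[2]:hi[2]) for (ii in lo[1]:hi[1]) {
      if (sum((c(ii, jj, kk) - centre)^2) <= r^2)
        data[ii, jj, kk] <- values[b]
    }
  }
  if (over_limit)
    image_volume(data, spec$affine, intent = "label")
  else
    label_map(data, spec$affine)
}

#' Generate helical tractogram fixtures
#'
#' Streamline `s` is a helix with analytic coordinates
#' `centre + (r cos(theta), r sin(theta), c * theta)` sampled at
#' `theta = theta0 + (k-1) * dtheta`, `k = 1..n_points`; radius, pitch,
#' phase and point count are drawn deterministically from `seed`.
#'
#' @param n_streamlines number of streamlines (>= 0).
#' @param seed integer seed.
#' @param n_points_range inclusive range of points per streamline.
#' @return a [tractogram()] in RAS millimetres.
#' @export
make_helical_tracts <- function(n_streamlines, seed = 1L,
                                n_points_range = c(10L, 60L)) {
  if (n_streamlines < 0L) stop_input("n_streamlines must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  streamlines <- lapply(seq_len(n_streamlines), function(s) {
    n <- sample(n_points_range[1]:n_points_range[2], 1L)
    r <- stats::runif(1, 5, 30)
    cc <- stats::runif(1, 0.5, 3)
    theta0 <- stats::runif(1, 0, 2 * pi)
    centre <- stats::runif(3, -40, 40)
    theta <- theta0 + (seq_len(n) - 1L) * 0.1
    cbind(centre[1] + r * cos(theta),
          centre[2] + r * sin(theta),
          centre[3] + cc * theta)
  })
  tractogram(streamlines,
             header = c(timestamp = "0", generated_by = "dicomnav fixtures"))
}

#' Write a minimal template DICOM file
#'
#' Emits the smallest Part-10 file carrying the whitelisted
#' patient/study/institution attributes plus required file meta, loadable
#' by [load_template()] and by standard DICOM readers.  This is a
#' synthetic stand-in for a clinical session file.
#'
#' @param patient_fields named list of whitelisted attribute values, e.g.
#'   `list(PatientID = "SYN01", PatientName = "Synthetic^Subject")`.
#'   Omitted attributes are simply absent from the file.
#' @param path output path.
#' @param ctx optional [series_context()] used to mint the template's own
#'   UIDs (a fresh one is created otherwise).
#' @return `path`, invisibly.
#' @export
make_minimal_template_dicom <- function(patient_fields, path, ctx = NULL) {
  if (is.null(ctx)) ctx <- series_context(rng_seed = 20260920L)
  bad <- setdiff(names(patient_fields), .TEMPLATE_WHITELIST)
  if (length(bad))
    stop_input("not whitelisted template attributes: ",
               paste(bad, collapse = ", "))
  ds <- dcm_ds(
    SOPClassUID = DCM_UID$secondary_capture,
    SOPInstanceUID = new_uid(ctx),
    StudyInstanceUID = if (!is.null(patient_fields$StudyInstanceUID))
      patient_fields$StudyInstanceUID else new_uid(ctx),
    SeriesInstanceUID = new_uid(ctx),
    Modality = "OT",
    SeriesNumber = 1L,
    InstanceNumber = 1L
  )
  for (kw in setdiff(names(patient_fields), "StudyInstanceUID"))
    ds <- c(ds, list(dcm_el(kw, patient_fields[[kw]])))
  write_dicom_file(ds, path, transfer_syntax = DCM_UID$explicit_vr_le)
  invisible(path)
}

#' Materialise a complete synthetic demo workup
#'
#' Writes a template DICOM, structural NIfTI volumes, label NIfTI images
#' and tck tractograms into a directory, ready to drive a full conversion.
#'
#' @param dir target directory (created).
#' @param seed integer seed.
#' @param shape voxel extents of the volumes.
#' @param n_structural,n_tracts,n_labels how many of each input to create.
#' @return named list of created file paths.
#' @export
make_demo_workup <- function(dir, seed = 1L, shape = c(24L, 24L, 16L),
                             n_structural = 1L, n_tracts = 2L, n_labels = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  template <- file.path(dir, "template.dcm")
  make_minimal_template_dicom(list(
    PatientID = "SYN01", PatientName = "Synthetic^Subject",
    PatientBirthDate = "20100101", PatientSex = "O",
    StudyDate = "20260101", StudyTime = "101010",
    StudyDescription = "synthetic workup",
    InstitutionName = "Synthetic Institute"
  ), template, ctx = series_context(rng_seed = seed))

  structural <- character(n_structural)
  for (s in seq_len(n_structural)) {
    vol <- make_phantom_volume(phantom_spec(shape, seed = seed + s,
                                            content = "sphere"))
    structural[s] <- file.path(dir, sprintf("structural%d.nii.gz", s))
    write_nifti_volume(vol, structural[s])
  }

  tracts <- character(n_tracts)
  for (s in seq_len(n_tracts)) {
    tck <- make_helical_tracts(20L, seed = seed + 100L + s)
    tracts[s] <- file.path(dir, sprintf("tract%d.tck", s))
    write_tck(tck, tracts[s])
  }

  labels <- character(n_labels)
  for (s in seq_len(n_labels)) {
    lm <- make_label_blobs(3L, phantom_spec(shape, seed = seed))
    labels[s] <- file.path(dir, sprintf("labels%d.nii.gz", s))
    write_nifti_volume(lm, labels[s])
  }

  list(template = template, structural = structural, tracts = tracts,
       labels = labels)
}
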