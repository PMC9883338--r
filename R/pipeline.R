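# End-to-end conversion: one command turns a template DICOM, >=1 structural
# NIfTI images, optional tck tractograms and optional NIfTI label maps into
# a DICOM directory ready for navigation-suite import.  Every emitted
# object shares one frame-of-reference UID; inputs are assumed coregistered
# and never resampled or checked.

#' Describe a conversion job
#'
#' @param template_path template DICOM file supplying patient/institution
#'   attributes.
#' @param structural_paths ordered character vector (>= 1) of structural
#'   NIfTI paths; tract objects derive from the first.
#' @param tract_paths character vector (>= 0) of MRtrix `.tck` paths.
#' @param label_paths character vector (>= 0) of NIfTI label-map paths;
#'   each must geometry-match one structural input.
#' @param output_dir target directory (created if absent).
#' @param seed optional integer for deterministic UID generation.
#' @param strict strict tck count checking (see [read_tck()]).
#' @param new_study_uid mint a fresh study UID instead of joining the
#'   template's study.
#' @param label_names optional path to a JSON file mapping label values to
#'   segment names, e.g. `{"1": "tumour", "2": "activation"}`.
#' @param fixed_clock optional `"YYYYMMDDHHMMSS"` content timestamp for
#'   byte-identical reruns.
#' @return an object of class `conversion_job`.
#' @export
conversion_job <- function(template_path, structural_paths,
                           tract_paths = character(), label_paths = character(),
                           output_dir, seed = NULL, strict = TRUE,
                           new_study_uid = FALSE, label_names = NULL,
                           fixed_clock = NULL) {
  if (length(structural_paths) < 1L)
    stop_usage("at least one structural image (--nifti) is required")
  if (missing(template_path) || length(template_path) != 1L)
    stop_usage("exactly one template DICOM (--dicom-template) is required")
  if (missing(output_dir) || length(output_dir) != 1L)
    stop_usage("an output directory (--output-dir) is required")
  if (!file.exists(template_path))
    stop_usage("template DICOM not found: ", template_path)
  missing_structural <- structural_paths[!file.exists(structural_paths)]
  if (length(missing_structural))
    stop_usage("structural image not found: ",
               paste(missing_structural, collapse = ", "))
  for (p in c(tract_paths, label_paths))
    if (!file.exists(p)) stop_usage("input file not found: ", p)
  structure(list(
    template_path = template_path,
    structural_paths = structural_paths,
    tract_paths = tract_paths,
    label_paths = label_paths,
    output_dir = output_dir,
    options = list(seed = seed, strict = strict,
                   new_study_uid = new_study_uid,
                   label_names = label_names, fixed_clock = fixed_clock)
  ), class = "conversion_job")
}

.log_msg <- function(...) message("[dicomnav] ", ...)

#' Run a conversion job
#'
#' Converts every input and writes the DICOM output directory plus a
#' `manifest.json` recording every input-to-output mapping, all UIDs, and
#' every decision taken (study UID policy, slice flips, geometry matches).
#' On failure, partially written DICOM files are removed and the directory
#' is left holding only a manifest describing the failure; the error is
#' then re-raised.
#'
#' @param job a [conversion_job()].
#' @return the manifest, invisibly.
#' @export
run_conversion <- function(job) {
  stopifnot(inherits(job, "conversion_job"))
  outdir <- job$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "dicomnav importTractography",
    version = .IMPLEMENTATION_VERSION,
    status = "running",
    inputs = list(template = job$template_path,
                  structural = as.list(job$structural_paths),
                  tracts = as.list(job$tract_paths),
                  labels = as.list(job$label_paths)),
    decisions = list(),
    outputs = list(),
    warnings = list()
  )
  written <- character(0)
  note <- function(...) {
    manifest$decisions[[length(manifest$decisions) + 1L]] <<- paste0(...)
    .log_msg(...)
  }

  finish_fail <- function(cond) {
    for (f in written) unlink(f)
    # drop now-empty series directories
    for (d in list.dirs(outdir, recursive = FALSE))
      if (length(list.files(d, recursive = TRUE)) == 0L) unlink(d, recursive = TRUE)
    manifest$status <<- "failed"
    manifest$error <<- conditionMessage(cond)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    stop(cond)
  }

  tryCatch({
    ctx <- series_context(rng_seed = job$options$seed,
                          fixed_clock = job$options$fixed_clock)
    meta <- load_template(job$template_path)
    template_study <- meta$attributes$StudyInstanceUID
    if (!job$options$new_study_uid && !is.null(template_study)) {
      ctx$study_uid <- template_study
      note("study UID copied from template (converted objects join the ",
           "original study)")
    } else {
      ctx$study_uid <- new_uid(ctx)
      note(if (job$options$new_study_uid)
        "fresh study UID minted (--new-study-uid)" else
        "template carries no study UID; fresh study UID minted")
    }
    manifest$study_uid <- ctx$study_uid
    manifest$frame_of_reference_uid <- ctx$frame_of_reference_uid

    label_names <- NULL
    if (!is.null(job$options$label_names)) {
      ln <- jsonlite::read_json(job$options$label_names)
      label_names <- vapply(ln, as.character, "")
      names(label_names) <- names(ln)
    }

    series_list <- list()
    for (sp in job$structural_paths) {
      vol <- read_nifti_volume(sp, intent = "structural")
      series <- volume_to_mr_series(vol, meta, ctx)
      if (series$geometry$flip_slices)
        note("left-handed voxel grid in ", sp,
             ": slice order flipped for export")
      paths <- write_mr_series(series, outdir)
      written <- c(written, paths)
      series_list[[length(series_list) + 1L]] <- series
      manifest$outputs[[length(manifest$outputs) + 1L]] <- list(
        kind = "mr_series", input = sp, series_uid = series$series_uid,
        series_number = series$series_number, n_instances = length(paths),
        files = as.list(file.path(basename(dirname(paths)), basename(paths))))
      .log_msg("MR series ", series$series_number, " (", length(paths),
               " instances) <- ", sp)
    }

    for (ti in seq_along(job$tract_paths)) {
      tp <- job$tract_paths[ti]
      tract <- withCallingHandlers(
        read_tck(tp, strict = job$options$strict),
        warning = function(w) {
          manifest$warnings[[length(manifest$warnings) + 1L]] <<-
            conditionMessage(w)
          invokeRestart("muffleWarning")
        })
      color <- .SEGMENT_PALETTE[(ti - 1L) %% 30L + 1L, ]
      surf <- tractogram_to_surface(tract, series_list[[1]], meta, ctx,
                                    color = color)
      path <- write_surface_object(surf, outdir)
      written <- c(written, path)
      note("tract object from ", tp, " derives from first structural series ",
           series_list[[1]]$series_uid)
      manifest$outputs[[length(manifest$outputs) + 1L]] <- list(
        kind = "surface_tract", input = tp, series_uid = surf$series_uid,
        series_number = surf$series_number,
        n_streamlines = nrow(surf$runs), n_points = surf$n_points,
        derived_from = series_list[[1]]$series_uid,
        files = list(file.path(basename(dirname(path)), basename(path))))
      .log_msg("Surface object ", surf$series_number, " <- ", tp)
    }

    for (lp in job$label_paths) {
      lm <- read_label_map(lp)
      match_idx <- NULL
      for (si in seq_along(series_list)) {
        if (geometry_matches(lm$affine, dim(lm$data),
                             series_list[[si]]$affine, series_list[[si]]$shape)) {
          match_idx <- si
          break
        }
      }
      if (is.null(match_idx))
        stop_geometry("label image ", lp, " matches no structural input: ",
                      "voxel size, spacing and orientation must match one ",
                      "of the --nifti images")
      note("label image ", lp, " geometry-matched to structural input ",
           match_idx, " (", job$structural_paths[match_idx], ")")
      seg <- labelmap_to_seg(lm, series_list[[match_idx]], meta, ctx,
                             segment_labels = label_names)
      path <- write_seg_object(seg, outdir)
      written <- c(written, path)
      manifest$outputs[[length(manifest$outputs) + 1L]] <- list(
        kind = "segmentation", input = lp, series_uid = seg$series_uid,
        series_number = seg$series_number,
        n_segments = nrow(seg$segments), n_frames = nrow(seg$frames),
        derived_from = series_list[[match_idx]]$series_uid,
        files = list(file.path(basename(dirname(path)), basename(path))))
      .log_msg("SEG object ", seg$series_number, " (", nrow(seg$segments),
               " segments) <- ", lp)
    }

    manifest$status <- "ok"
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    invisible(manifest)
  }, error = finish_fail)
}

#' Parse importTractography command-line arguments
#'
#' Understands the flags `--dicom-template`, `--nifti`, `--tract-files`,
#' `--label-files`, `--output-dir` (each of the multi-valued flags consumes
#' every following token up to the next flag) plus the extensions `--seed`,
#' `--lenient`, `--new-study-uid`, `--label-names`, `--fixed-clock`.
#'
#' @param argv character vector of command-line tokens.
#' @return a [conversion_job()].
#' @export
parse_import_args <- function(argv) {
  flags <- list(`--dicom-template` = character(), `--nifti` = character(),
                `--tract-files` = character(), `--label-files` = character(),
                `--output-dir` = character(), `--seed` = character(),
                `--label-names` = character(), `--fixed-clock` = character())
  switches <- c(`--lenient` = FALSE, `--new-study-uid` = FALSE)
  current <- NULL
  for (tok in argv) {
    if (tok %in% names(switches)) {
      switches[tok] <- TRUE
      current <- NULL
    } else if (tok %in% names(flags)) {
      current <- tok
    } else if (startsWith(tok, "--")) {
      stop_usage("unknown option: ", tok)
    } else {
      if (is.null(current)) stop_usage("unexpected argument: ", tok)
      flags[[current]] <- c(flags[[current]], tok)
    }
  }
  if (length(flags$`--dicom-template`) != 1L)
    stop_usage("--dicom-template requires exactly one file")
  if (length(flags$`--output-dir`) != 1L)
    stop_usage("--output-dir requires exactly one directory")
  if (length(flags$`--nifti`) < 1L)
    stop_usage("--nifti requires at least one image")
  seed <- if (length(flags$`--seed`)) as.integer(flags$`--seed`[1]) else NULL
  conversion_job(
    template_path = flags$`--dicom-template`,
    structural_paths = flags$`--nifti`,
    tract_paths = flags$`--tract-files`,
    label_paths = flags$`--label-files`,
    output_dir = flags$`--output-dir`,
    seed = seed,
    strict = !switches["--lenient"],
    new_study_uid = switches["--new-study-uid"],
    label_names = if (length(flags$`--label-names`))
      flags$`--label-names`[1] else NULL,
    fixed_clock = if (length(flags$`--fixed-clock`))
      flags$`--fixed-clock`[1] else NULL
  )
}

#' Command-line entry point
#'
#' Thin wrapper used by the `importTractography` script: parses `argv`,
#' runs the conversion, and returns a process exit status (0 success,
#' 2 usage error, 3 input format error, 4 geometry error).
#'
#' @param argv character vector of command-line tokens (defaults to the
#'   running script's arguments).
#' @return integer exit status, invisibly.
#' @export
import_tractography_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    job <- parse_import_args(argv)
    run_conversion(job)
    0L
  }, dicomnav_error = function(e) {
    message("error: ", conditionMessage(e))
    exit_code_for_condition(e)
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
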