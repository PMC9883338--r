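# Classed conditions so the CLI can map failure modes to exit codes:
#   usage (2), input format (3), geometry (4).

.stop_classed <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(
    class = c(class, "dicomnav_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_usage <- function(...) .stop_classed("dicomnav_usage_error", ...)
stop_format <- function(...) .stop_classed("dicomnav_format_error", ...)
stop_geometry <- function(...) .stop_classed("dicomnav_geometry_error", ...)
stop_input <- function(...) .stop_classed("dicomnav_input_error", ...)
stop_corrupt <- function(...) .stop_classed(
  c("dicomnav_corrupt_error", "dicomnav_format_error"), ...)

exit_code_for_condition <- function(cond) {
  if (inherits(cond, "dicomnav_usage_error")) return(2L)
  if (inherits(cond, "dicomnav_format_error")) return(3L)
  if (inherits(cond, "dicomnav_input_error")) return(3L)
  if (inherits(cond, "dicomnav_geometry_error")) return(4L)
  1L
}
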