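# UID generation and the per-conversion series context.
#
# All objects emitted by one conversion run share a study UID and a frame of
# reference UID drawn from one series_context.  UIDs use the "2.25." UUID-
# derived numeric root followed by 30 decimal digits from an internal linear
# congruential generator, so UID generation never disturbs the user's R RNG
# stream.  When `rng_seed` is supplied the digit stream is deterministic,
# giving reproducible UID sets for tests and audits.

.lcg_next <- function(state) {
  # Park-Miller minimal standard generator, modulus 2^31 - 1
  (16807 * state) %% 2147483647
}

.ctx_digits <- function(ctx, n) {
  d <- integer(n)
  for (i in seq_len(n)) {
    ctx$state <- .lcg_next(ctx$state)
    d[i] <- ctx$state %% 10L
  }
  d
}

#' Create a series context for one conversion run
#'
#' The series context holds the identifiers shared across every DICOM object
#' emitted by a single conversion: the study instance UID, the common frame
#' of reference UID, and a series-number counter.  It also owns UID
#' generation.
#'
#' @param rng_seed optional integer; when given, all generated UIDs are a
#'   deterministic function of the seed (reproducible runs).  When `NULL`,
#'   the generator is seeded from the wall clock and process id.
#' @param uid_root organisational UID prefix; the default `"2.25"` is the
#'   standard UUID-derived numeric root.
#' @param fixed_clock optional `"YYYYMMDDHHMMSS"` string used for content
#'   date/time attributes instead of the current time (for byte-identical
#'   reruns).
#' @return an environment of class `series_context`.
#' @export
series_context <- function(rng_seed = NULL, uid_root = "2.25",
                           fixed_clock = NULL) {
  ctx <- new.env(parent = emptyenv())
  ctx$uid_root <- uid_root
  ctx$rng_seed <- rng_seed
  seed <- if (is.null(rng_seed)) {
    floor(as.numeric(Sys.time()) * 1000 + Sys.getpid()) %% 2147483646 + 1
  } else {
    (abs(floor(as.numeric(rng_seed))) %% 2147483646) + 1
  }
  ctx$state <- seed
  ctx$next_series_number <- 1L
  ctx$fixed_clock <- fixed_clock
  ctx$study_uid <- NULL          # set once the template is loaded
  ctx$frame_of_reference_uid <- NULL
  class(ctx) <- "series_context"
  ctx$frame_of_reference_uid <- new_uid(ctx)
  ctx
}

#' Generate a DICOM UID
#'
#' Produces a UID of the form `<uid_root>.<30 digits>` with no leading zero
#' in the final component, at most 64 characters, digits and dots only.
#'
#' @param ctx a [series_context()].
#' @return a UID string.
#' @export
new_uid <- function(ctx) {
  d <- .ctx_digits(ctx, 30L)
  if (d[1] == 0L) d[1] <- 1L + (d[2] %% 9L)
  uid <- paste0(ctx$uid_root, ".", paste(d, collapse = ""))
  stopifnot(nchar(uid) <= 64L)
  uid
}

next_series_number <- function(ctx) {
  n <- ctx$next_series_number
  ctx$next_series_number <- n + 1L
  n
}

ctx_date_time <- function(ctx) {
  if (!is.null(ctx$fixed_clock)) {
    s <- gsub("[^0-9]", "", ctx$fixed_clock)
    return(list(date = substr(s, 1, 8), time = substr(s, 9, 14)))
  }
  now <- Sys.time()
  list(date = format(now, "%Y%m%d"), time = format(now, "%H%M%S"))
}
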