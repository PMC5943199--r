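#' Dynamic frame schema
#'
#' A `frame_schema` holds the time binning of a dynamic PET acquisition:
#' frame start times and frame durations, both in seconds from injection.
#' Frames must be strictly ordered and non-overlapping (gaps are allowed).
#'
#' @param starts Numeric vector of frame start times, seconds from injection.
#' @param durations Numeric vector of frame durations, seconds.
#' @return An object of class `frame_schema`.
#' @examples
#' sch <- frame_schema(c(0, 5, 10), c(5, 5, 5))
#' n_frames(sch)
#' @seealso [default_frame_schema()], [frame_midpoints()]
#' @export
frame_schema <- function(starts, durations) {
  starts <- as.numeric(starts)
  durations <- as.numeric(durations)
  if (length(starts) != length(durations))
    stop("'starts' and 'durations' must have the same length", call. = FALSE)
  if (anyNA(starts) || anyNA(durations))
    stop("frame schema must not contain NA", call. = FALSE)
  if (length(starts)) {
    if (starts[1] < 0)
      stop("first frame must start at or after injection (start >= 0)", call. = FALSE)
    if (any(durations <= 0))
      stop("frame durations must be positive", call. = FALSE)
    if (length(starts) > 1) {
      if (any(diff(starts) <= 0))
        stop("frame starts must be strictly increasing", call. = FALSE)
      ends <- starts + durations
      if (any(starts[-1] < ends[-length(ends)] - 1e-9))
        stop("frames must not overlap", call. = FALSE)
    }
  }
  structure(list(starts = starts, durations = durations), class = "frame_schema")
}

#' Default dynamic frame schema (30-min renal protocol)
#'
#' The re-binning used for a 30-minute dynamic renal acquisition:
#' 60 frames of 5 s followed by 25 frames of 60 s, 85 frames spanning
#' 1800 s in total.
#'
#' @return A `frame_schema` with 85 frames.
#' @export
default_frame_schema <- function() {
  frame_schema(
    starts    = c(seq(0, by = 5, length.out = 60), seq(300, by = 60, length.out = 25)),
    durations = c(rep(5, 60), rep(60, 25))
  )
}

#' Number of frames in a schema
#' @param schema A `frame_schema`.
#' @return Integer frame count.
#' @export
n_frames <- function(schema) {
  stopifnot(inherits(schema, "frame_schema"))
  length(schema$starts)
}

#' Frame midpoint times
#'
#' The time base used by all estimators: the midpoint of each frame,
#' converted to minutes post-injection.
#'
#' @param schema A `frame_schema`.
#' @return Numeric vector of midpoints in minutes, strictly increasing.
#' @export
frame_midpoints <- function(schema) {
  stopifnot(inherits(schema, "frame_schema"))
  (schema$starts + schema$durations / 2) / 60
}

#' Frame end times in seconds
#' @param schema A `frame_schema`.
#' @return Numeric vector of frame end times, seconds.
#' @export
frame_ends <- function(schema) {
  stopifnot(inherits(schema, "frame_schema"))
  schema$starts + schema$durations
}

#' Total time span of a schema in minutes
#'
#' From injection (t = 0) to the end of the last frame.
#' @param schema A `frame_schema`.
#' @return Span in minutes.
#' @export
schema_span_min <- function(schema) {
  stopifnot(inherits(schema, "frame_schema"))
  if (!length(schema$starts)) return(0)
  max(frame_ends(schema)) / 60
}

#' @export
print.frame_schema <- function(x, ...) {
  n <- length(x$starts)
  cat(sprintf("frame_schema: %d frames, %g-%g s\n", n,
              if (n) x$starts[1] else NA, if (n) max(frame_ends(x)) else NA))
  invisible(x)
}

schemas_identical <- function(a, b) {
  length(a$starts) == length(b$starts) &&
    isTRUE(all.equal(a$starts, b$starts, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$durations, b$durations, tolerance = 1e-9))
}
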