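#' Time-activity curve
#'
#' A `tac` couples a [frame_schema()] with one tracer concentration value per
#' frame (kBq/ml, decay-corrected). Negative values, which can arise from
#' reconstruction or smoothing, are clipped to zero because concentration is
#' physically non-negative.
#'
#' @param schema A `frame_schema`.
#' @param values Numeric vector, one concentration (kBq/ml) per frame.
#' @param label VOI name, e.g. `"aorta"`, `"left_kidney"`.
#' @param smoothed Logical; `TRUE` when the curve has been through
#'   [smooth_bezier()].
#' @param warn_clip Warn when negative values are clipped to zero.
#' @return An object of class `tac`.
#' @export
tac <- function(schema, values, label = "tac", smoothed = FALSE, warn_clip = TRUE) {
  stopifnot(inherits(schema, "frame_schema"))
  values <- as.numeric(values)
  if (length(values) != n_frames(schema))
    stop("length of 'values' must equal the number of frames", call. = FALSE)
  if (any(!is.finite(values)))
    stop("TAC values must be finite", call. = FALSE)
  if (any(values < 0)) {
    if (warn_clip)
      warning(sprintf("%d negative concentration value(s) clipped to 0 in '%s'",
                      sum(values < 0), label), call. = FALSE)
    values[values < 0] <- 0
  }
  structure(list(schema = schema, values = values, label = label,
                 smoothed = isTRUE(smoothed)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("tac '%s': %d frames, max %.3g kBq/ml%s\n", x$label,
              length(x$values), if (length(x$values)) max(x$values) else NA,
              if (x$smoothed) " (smoothed)" else ""))
  invisible(x)
}

#' Read a TAC table
#'
#' Reads a comma-separated table with header columns `frame_start_s`,
#' `frame_duration_s` and one additional column per VOI. All VOI columns
#' share one frame schema; concentrations are taken as kBq/ml.
#'
#' @param path Path to a CSV file.
#' @return Named list of [tac()] objects, one per VOI column.
#' @export
read_tac_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("frame_start_s", "frame_duration_s")
  if (anyDuplicated(names(df)))
    stop("duplicate column names in TAC table", call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("TAC table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  voi_cols <- setdiff(names(df), required)
  if (!length(voi_cols))
    stop("TAC table has no VOI columns", call. = FALSE)
  for (cn in c(required, voi_cols))
    if (!is.numeric(df[[cn]]))
      stop(sprintf("column '%s' contains non-numeric cells", cn), call. = FALSE)
  schema <- frame_schema(df$frame_start_s, df$frame_duration_s)
  out <- lapply(voi_cols, function(cn) tac(schema, df[[cn]], label = cn))
  names(out) <- voi_cols
  out
}

#' Write a TAC table
#'
#' Inverse of [read_tac_table()]: writes the shared frame schema plus one
#' column per TAC, in the same CSV dialect, so that a read/write round trip
#' is value-exact.
#'
#' @param tacs Named list of [tac()] objects sharing one schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(tacs, path) {
  stopifnot(length(tacs) >= 1, all(vapply(tacs, inherits, TRUE, "tac")))
  schema <- tacs[[1]]$schema
  for (tc in tacs)
    if (!schemas_identical(tc$schema, schema))
      stop("all TACs must share one frame schema", call. = FALSE)
  labels <- names(tacs)
  if (is.null(labels)) labels <- vapply(tacs, `[[`, "", "label")
  df <- data.frame(frame_start_s = schema$starts,
                   frame_duration_s = schema$durations, check.names = FALSE)
  for (i in seq_along(tacs)) df[[labels[i]]] <- tacs[[i]]$values
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bezier TAC smoothing
#'
#' Smooths a TAC with a sliding-window Bezier filter: around each frame, a
#' quadratic Bezier segment (Bernstein basis) is least-squares fitted to the
#' neighbouring frame points on the frame-midpoint time base and evaluated at
#' that frame's midpoint. Because the Bernstein basis of degree 2 spans the
#' quadratic polynomials, the filter reproduces constant, linear and
#' quadratic curves exactly (hence it is idempotent on them), while damping
#' frame-to-frame fluctuations in noisy data. At the two boundary frames the
#' window degenerates to three points, so the fit interpolates and endpoint
#' values are preserved exactly.
#'
#' @param x A [tac()].
#' @param half_width Window half-width in frames (default 2, i.e. 5-point
#'   windows in the interior).
#' @return A smoothed [tac()] with the `smoothed` flag set.
#' @export
smooth_bezier <- function(x, half_width = 2L) {
  stopifnot(inherits(x, "tac"))
  n <- length(x$values)
  if (n < 3) stop("smoothing needs at least 3 frames", call. = FALSE)
  half_width <- max(1L, as.integer(half_width))
  t <- frame_midpoints(x$schema)
  v <- x$values
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_width)
    hi <- min(n, i + half_width)
    idx <- lo:hi
    if (length(idx) < 3) { out[i] <- v[i]; next }
    # normalize window time to u in [0, 1]; degree-2 Bernstein design
    u <- (t[idx] - t[lo]) / (t[hi] - t[lo])
    B <- cbind((1 - u)^2, 2 * u * (1 - u), u^2)
    ctrl <- qr.coef(qr(B), v[idx])
    ui <- (t[i] - t[lo]) / (t[hi] - t[lo])
    out[i] <- sum(ctrl * c((1 - ui)^2, 2 * ui * (1 - ui), ui^2))
  }
  tac(x$schema, out, label = x$label, smoothed = TRUE, warn_clip = FALSE)
}

#' Detect the vascular peak of a TAC
#'
#' Finds the global maximum of the curve within the first `search_end_min`
#' minutes (the initial blood flush) and the peak onset ("rise"): the last
#' frame before the maximum whose baseline-corrected value is at or below
#' `rise_frac` of the baseline-corrected maximum. The baseline is the curve
#' minimum between injection and the maximum.
#'
#' @param x A [tac()] (smoothing recommended first).
#' @param search_end_min Restrict the peak search to midpoints at or before
#'   this time (minutes); default 5, the window of the initial blood flush.
#' @param rise_frac Rise threshold as a fraction of the baseline-corrected
#'   maximum; default 0.05.
#' @return An object of class `peak_descriptor` with elements `rise_index`,
#'   `max_index` (1-based frame indices), `p_max` (kBq/ml), `rise_time` and
#'   `max_time` (minutes).
#' @export
detect_peak <- function(x, search_end_min = 5, rise_frac = 0.05) {
  stopifnot(inherits(x, "tac"))
  t <- frame_midpoints(x$schema)
  v <- x$values
  in_search <- which(t <= search_end_min)
  if (!length(in_search)) stop("no frames within the peak search window", call. = FALSE)
  if (all(v[in_search] <= 0))
    stop("degenerate peak: curve is zero within the search window", call. = FALSE)
  max_index <- in_search[which.max(v[in_search])]
  p_max <- v[max_index]
  if (max_index == 1L)
    stop("degenerate peak: maximum at the first frame with no rise", call. = FALSE)
  baseline <- min(v[1:max_index])
  if (p_max - baseline <= 0)
    stop("degenerate peak: curve has no rise before its maximum", call. = FALSE)
  thr <- baseline + rise_frac * (p_max - baseline)
  below <- which(v[seq_len(max_index - 1L)] <= thr)
  if (!length(below))
    stop("degenerate peak: no frame at or below the rise threshold before the maximum",
         call. = FALSE)
  rise_index <- max(below)
  peak_descriptor(rise_index, max_index, p_max,
                  rise_time = t[rise_index], max_time = t[max_index])
}

#' Construct a peak descriptor
#'
#' Usually produced by [detect_peak()]; the constructor is exported so that a
#' window anchor can be supplied by hand (e.g. anchoring at the first frame
#' for a curve without a vascular bump).
#'
#' @param rise_index,max_index 1-based frame indices, `rise_index <= max_index`.
#' @param p_max Concentration at the maximum, kBq/ml.
#' @param rise_time,max_time Frame-midpoint times in minutes.
#' @return An object of class `peak_descriptor`.
#' @export
peak_descriptor <- function(rise_index, max_index, p_max, rise_time, max_time) {
  rise_index <- as.integer(rise_index); max_index <- as.integer(max_index)
  if (rise_index > max_index)
    stop("rise_index must not exceed max_index", call. = FALSE)
  structure(list(rise_index = rise_index, max_index = max_index,
                 p_max = as.numeric(p_max), rise_time = as.numeric(rise_time),
                 max_time = as.numeric(max_time)),
            class = "peak_descriptor")
}

#' @export
print.peak_descriptor <- function(x, ...) {
  cat(sprintf("peak: max %.3g kBq/ml at frame %d (%.2f min), rise at frame %d (%.2f min)\n",
              x$p_max, x$max_index, x$max_time, x$rise_index, x$rise_time))
  invisible(x)
}

#' Integrate a TAC over a time interval
#'
#' Trapezoidal integration of the piecewise-linear curve through the
#' frame-midpoint samples, with linear interpolation at the interval
#' boundaries. Outside the midpoint range the curve is extended as a
#' constant (nearest frame value), so integration may start at injection
#' (t = 0) and end at the close of the last frame.
#'
#' @param x A [tac()].
#' @param t_start_min,t_end_min Integration bounds in minutes,
#'   `0 <= t_start_min < t_end_min <= ` end of last frame.
#' @return Integral in kBq/ml * min.
#' @export
integrate_tac <- function(x, t_start_min, t_end_min) {
  stopifnot(inherits(x, "tac"))
  if (!is.finite(t_start_min) || !is.finite(t_end_min) || t_start_min >= t_end_min)
    stop("need t_start_min < t_end_min", call. = FALSE)
  span_end <- schema_span_min(x$schema)
  if (t_start_min < 0 || t_end_min > span_end + 1e-9)
    stop(sprintf("integration range [%g, %g] outside curve span [0, %g] min",
                 t_start_min, t_end_min, span_end), call. = FALSE)
  grid <- tac_grid(x)
  trapz_interval(grid$t, grid$v, t_start_min, t_end_min)
}

# piecewise-linear node grid of a tac: midpoints plus constant extension
# to t = 0 and to the end of the last frame
tac_grid <- function(x) {
  t <- frame_midpoints(x$schema)
  v <- x$values
  n <- length(t)
  t_end <- schema_span_min(x$schema)
  if (n == 0) return(list(t = numeric(0), v = numeric(0)))
  tt <- t; vv <- v
  if (t[1] > 0) { tt <- c(0, tt); vv <- c(v[1], vv) }
  if (t[n] < t_end) { tt <- c(tt, t_end); vv <- c(vv, v[n]) }
  list(t = tt, v = vv)
}

# exact trapezoid integral of the piecewise-linear curve (t, v) over [a, b]
trapz_interval <- function(t, v, a, b) {
  va <- stats::approx(t, v, xout = a, rule = 2)$y
  vb <- stats::approx(t, v, xout = b, rule = 2)$y
  inner <- which(t > a & t < b)
  tt <- c(a, t[inner], b)
  vv <- c(va, v[inner], vb)
  sum(diff(tt) * (vv[-length(vv)] + vv[-1]) / 2)
}

#' Cumulative integral of a TAC from injection to each frame midpoint
#'
#' @param x A [tac()].
#' @return Numeric vector: `integrate_tac(x, 0, t_i)` for every frame
#'   midpoint `t_i`, in kBq/ml * min.
#' @export
cumulative_integral <- function(x) {
  stopifnot(inherits(x, "tac"))
  t <- frame_midpoints(x$schema)
  v <- x$values
  n <- length(t)
  if (!n) return(numeric(0))
  out <- numeric(n)
  out[1] <- v[1] * t[1]  # constant extension back to injection
  if (n > 1)
    out[-1] <- out[1] + cumsum(diff(t) * (v[-n] + v[-1]) / 2)
  out
}
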