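#' Patlak transform of a tissue TAC against an input function
#'
#' For an irreversibly trapped tracer the tissue curve obeys
#' \deqn{C_t(t)/C_p(t) = K \int_0^t C_p(\tau) d\tau / C_p(t) + V_0}
#' so plotting y = C_t/Cp against the normalized time x = (integral of Cp)/Cp
#' linearizes the kinetics; the asymptotic slope is the net uptake constant K
#' (min^-1) and the intercept the apparent vascular volume fraction.
#'
#' Frames where the input function falls below `floor_frac` of its maximum
#' are excluded to avoid dividing by near-zero early values.
#'
#' @param tissue Tissue [tac()] (kidney or cortex).
#' @param aif Input-function [tac()] (aorta); same frame schema.
#' @param floor_frac Inclusion floor for the input function, as a fraction of
#'   its maximum; default 0.01.
#' @return An object of class `patlak_points`: data frame with columns `x`
#'   (min), `y` (unitless), `frame_index`, `time_min`.
#' @export
patlak_transform <- function(tissue, aif, floor_frac = 0.01) {
  stopifnot(inherits(tissue, "tac"), inherits(aif, "tac"))
  if (!schemas_identical(tissue$schema, aif$schema))
    stop("tissue and input function must share one frame schema", call. = FALSE)
  cp <- aif$values
  if (all(cp <= 0)) stop("input function is identically zero", call. = FALSE)
  floor <- floor_frac * max(cp)
  keep <- which(cp >= floor & cp > 0)
  if (!length(keep))
    stop("input function everywhere below the inclusion floor", call. = FALSE)
  cum <- cumulative_integral(aif)
  pts <- data.frame(
    x = cum[keep] / cp[keep],
    y = tissue$values[keep] / cp[keep],
    frame_index = keep,
    time_min = frame_midpoints(aif$schema)[keep]
  )
  class(pts) <- c("patlak_points", "data.frame")
  pts
}

#' Select the peak-anchored Patlak fit window
#'
#' The linear segment used for the GFR slope: from the point whose frame is
#' the tissue TAC peak maximum through the last point whose frame midpoint is
#' at or before `window_end_min` minutes post-injection (default 2).
#'
#' @param points A [patlak_transform()] result.
#' @param tissue_peak A [peak_descriptor()] computed on the same tissue TAC.
#' @param window_end_min Window end, minutes post-injection; default 2.
#' @return Integer vector of row indices into `points` (class
#'   `patlak_window`), with the covered frame range as attributes.
#' @export
select_fit_window <- function(points, tissue_peak, window_end_min = 2) {
  stopifnot(inherits(points, "patlak_points"), inherits(tissue_peak, "peak_descriptor"))
  rows <- which(points$frame_index >= tissue_peak$max_index &
                  points$time_min <= window_end_min + 1e-9)
  if (length(rows) < 3)
    stop(sprintf(
      "Patlak fit window holds %d point(s); need at least 3 (peak at %.2f min, window end %.2f min)",
      length(rows), tissue_peak$max_time, window_end_min), call. = FALSE)
  structure(rows, class = "patlak_window",
            first_frame = points$frame_index[rows[1]],
            last_frame = points$frame_index[rows[length(rows)]])
}

#' Fit the Patlak slope by ordinary least squares
#'
#' @param points A [patlak_transform()] result.
#' @param window Row indices from [select_fit_window()] (or any integer
#'   vector of at least 3 rows).
#' @return An object of class `patlak_fit` with elements `K` (slope, min^-1),
#'   `intercept`, `stderr_K`, `r_squared`, `window`, `n_points`.
#' @export
fit_patlak <- function(points, window) {
  stopifnot(inherits(points, "patlak_points"))
  rows <- as.integer(window)
  if (length(rows) < 3) stop("fit window needs at least 3 points", call. = FALSE)
  x <- points$x[rows]; y <- points$y[rows]
  if (max(x) - min(x) <= 0 || stats::var(x) == 0)
    stop("degenerate fit window: no spread in Patlak abscissa", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact data ("essentially perfect fit"); exact
  # constructed inputs are a supported case here
  sm <- suppressWarnings(summary(fit))
  K <- unname(stats::coef(fit)[2])
  structure(list(
    K = K,
    intercept = unname(stats::coef(fit)[1]),
    stderr_K = unname(sm$coefficients[2, 2]),
    r_squared = sm$r.squared,
    window = rows,
    n_points = length(rows),
    points = points
  ), class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("Patlak fit: K = %.4g min^-1 (SE %.2g), intercept = %.4g, r^2 = %.3f, %d points\n",
              x$K, x$stderr_K, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Kidney VOI volumes
#'
#' @param left_ml,right_ml Kidney (or cortex) VOI volumes in ml; must be
#'   positive. Values outside the plausibility band 20-400 ml per kidney
#'   trigger a warning, not an error.
#' @return An object of class `voi_volumes`.
#' @export
voi_volumes <- function(left_ml, right_ml) {
  left_ml <- as.numeric(left_ml); right_ml <- as.numeric(right_ml)
  if (length(left_ml) != 1 || length(right_ml) != 1 ||
      !is.finite(left_ml) || !is.finite(right_ml))
    stop("kidney volumes must be single finite numbers", call. = FALSE)
  if (left_ml <= 0 || right_ml <= 0)
    stop("kidney volumes must be positive", call. = FALSE)
  if (left_ml < 20 || left_ml > 400 || right_ml < 20 || right_ml > 400)
    warning("kidney volume outside the 20-400 ml plausibility band", call. = FALSE)
  structure(list(left_ml = left_ml, right_ml = right_ml), class = "voi_volumes")
}

#' GFR from Patlak slopes and kidney volumes
#'
#' \deqn{GFR [ml/min] = K_{right} V_{right} + K_{left} V_{left}}
#' with K in min^-1 and V in ml. A negative slope is physiologically
#' implausible; it is kept (with a warning) rather than clamped so the
#' diagnostic signal is not hidden.
#'
#' @param K_left,K_right Patlak slopes, min^-1.
#' @param volumes A [voi_volumes()].
#' @param stderr_left,stderr_right Standard errors of the slopes (min^-1);
#'   propagated to an ml/min error by root-sum-square of K-error times
#'   volume.
#' @param extra_error_pct Additional relative error component in percent of
#'   the total GFR (e.g. a VOI reproducibility term); combined by
#'   root-sum-square.
#' @return An object of class `gfr_estimate` with per-kidney and total GFR
#'   (ml/min) and the propagated `error_ml_min`.
#' @export
compute_gfr <- function(K_left, K_right, volumes,
                        stderr_left = 0, stderr_right = 0,
                        extra_error_pct = 0) {
  stopifnot(inherits(volumes, "voi_volumes"))
  if (!is.finite(K_left) || !is.finite(K_right))
    stop("Patlak slopes must be finite", call. = FALSE)
  if (K_left < 0 || K_right < 0)
    warning("negative Patlak slope: GFR estimate is not physiologically meaningful",
            call. = FALSE)
  gfr_left <- K_left * volumes$left_ml
  gfr_right <- K_right * volumes$right_ml
  total <- gfr_left + gfr_right
  err <- combine_errors(c(stderr_left * volumes$left_ml,
                          stderr_right * volumes$right_ml,
                          abs(extra_error_pct) / 100 * abs(total)))
  structure(list(K_left = K_left, K_right = K_right,
                 gfr_left_ml_min = gfr_left, gfr_right_ml_min = gfr_right,
                 gfr_total_ml_min = total, error_ml_min = err),
            class = "gfr_estimate")
}

#' @export
print.gfr_estimate <- function(x, ...) {
  cat(sprintf("GFR: %.1f ml/min (left %.1f + right %.1f), error %.1f ml/min\n",
              x$gfr_total_ml_min, x$gfr_left_ml_min, x$gfr_right_ml_min,
              x$error_ml_min))
  invisible(x)
}

#' Full Patlak GFR pipeline for one subject
#'
#' Smooths the curves (unless already smoothed or `smooth = FALSE`), detects
#' each kidney's TAC peak, Patlak-transforms each kidney against the aortic
#' input function, selects the peak-anchored window ending at
#' `window_end_min`, fits the slope and converts to ml/min via the VOI
#' volumes.
#'
#' @param aif Aorta [tac()].
#' @param left,right Kidney (or cortex) [tac()]s.
#' @param volumes A [voi_volumes()].
#' @param window_end_min Patlak window end in minutes post-injection
#'   (default 2).
#' @param smooth Apply [smooth_bezier()] to curves not yet smoothed.
#' @param floor_frac Input-function inclusion floor (see
#'   [patlak_transform()]).
#' @param rise_frac Peak rise threshold (see [detect_peak()]).
#' @param extra_error_pct Reproducibility error component in percent, added
#'   to the fit error by root-sum-square (default 7, the total-kidney VOI
#'   reproducibility variation).
#' @return A list of class `patlak_gfr_result`: `gfr` ([compute_gfr()]
#'   result), `fit_left`, `fit_right` ([fit_patlak()] results), `peaks`.
#' @export
patlak_gfr <- function(aif, left, right, volumes, window_end_min = 2,
                       smooth = TRUE, floor_frac = 0.01, rise_frac = 0.05,
                       extra_error_pct = 7) {
  prep <- function(x) if (smooth && !x$smoothed) smooth_bezier(x) else x
  aif_s <- prep(aif); left_s <- prep(left); right_s <- prep(right)
  one_side <- function(tissue, tissue_raw) {
    pk <- detect_peak(tissue, rise_frac = rise_frac)
    pts <- patlak_transform(tissue, aif_s, floor_frac = floor_frac)
    win <- select_fit_window(pts, pk, window_end_min = window_end_min)
    fit <- fit_patlak(pts, win)
    # smoothing correlates neighbouring frames and makes the OLS error of
    # the smoothed fit optimistic; take the slope uncertainty from the
    # unsmoothed tissue points over the same window instead
    if (!is.null(tissue_raw) && !identical(tissue_raw$values, tissue$values)) {
      raw_se <- tryCatch({
        pts_raw <- patlak_transform(tissue_raw, aif_s, floor_frac = floor_frac)
        rows <- match(pts$frame_index[win], pts_raw$frame_index)
        fit_patlak(pts_raw, rows[!is.na(rows)])$stderr_K
      }, error = function(e) NULL)
      if (!is.null(raw_se)) fit$stderr_K <- max(fit$stderr_K, raw_se)
    }
    list(fit = fit, peak = pk)
  }
  L <- one_side(left_s, left); R <- one_side(right_s, right)
  gfr <- compute_gfr(L$fit$K, R$fit$K, volumes,
                     stderr_left = L$fit$stderr_K,
                     stderr_right = R$fit$stderr_K,
                     extra_error_pct = extra_error_pct)
  structure(list(gfr = gfr, fit_left = L$fit, fit_right = R$fit,
                 peaks = list(left = L$peak, right = R$peak),
                 window_end_min = window_end_min),
            class = "patlak_gfr_result")
}

#' @export
print.patlak_gfr_result <- function(x, ...) {
  print(x$gfr)
  cat(sprintf("  K left %.4g, K right %.4g min^-1 (window end %g min)\n",
              x$gfr$K_left, x$gfr$K_right, x$window_end_min))
  invisible(x)
}
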