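# Subject-level orchestration: TAC table -> smoothing -> Patlak GFR + peak
# ERPF (-> optional input-function correction) -> machine-readable report,
# and the cohort-level method-agreement table.

#' Analysis configuration
#'
#' The defaults reproduce the method's stated rules exactly: Bezier
#' smoothing on, Patlak window ending 2 min post-injection anchored at the
#' TAC peak maximum, peak integral from rise to 1 min after rise, 5% rise
#' threshold, 1% input-function inclusion floor.
#'
#' @param window_end_min Patlak fit window end, minutes post-injection.
#' @param peak_width_min Peak integration width, minutes.
#' @param rise_frac Peak rise threshold (fraction of baseline-corrected
#'   maximum).
#' @param floor_frac Input-function inclusion floor (fraction of its
#'   maximum).
#' @param smooth Apply Bezier smoothing.
#' @param gfr_extra_error_pct,erpf_extra_error_pct Reproducibility error
#'   components in percent (defaults 7 and 7, the total-kidney VOI
#'   reproducibility variations).
#' @param aif_label,left_label,right_label Column names expected in the TAC
#'   table.
#' @return A list of class `run_config`.
#' @export
run_config <- function(window_end_min = 2, peak_width_min = 1,
                       rise_frac = 0.05, floor_frac = 0.01, smooth = TRUE,
                       gfr_extra_error_pct = 7, erpf_extra_error_pct = 7,
                       aif_label = "aorta", left_label = "left_kidney",
                       right_label = "right_kidney") {
  cfg <- list(window_end_min = window_end_min, peak_width_min = peak_width_min,
              rise_frac = rise_frac, floor_frac = floor_frac,
              smooth = isTRUE(smooth),
              gfr_extra_error_pct = gfr_extra_error_pct,
              erpf_extra_error_pct = erpf_extra_error_pct,
              aif_label = aif_label, left_label = left_label,
              right_label = right_label)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full kidney-function workflow for one subject
#'
#' @param tacs Path to a TAC table CSV (see [read_tac_table()]) or a named
#'   list of [tac()] objects containing the configured aorta and kidney
#'   labels.
#' @param volumes A [voi_volumes()] or numeric `c(left_ml, right_ml)`.
#' @param config A [run_config()].
#' @return A list of class `kidney_function_result` with `gfr`
#'   ([compute_gfr()] result), `erpf` ([compute_erpf()] result), the two
#'   Patlak fits (including the transformed points, for audit), the detected
#'   peaks and the configuration used.
#' @export
run_subject <- function(tacs, volumes, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(tacs)) tacs <- read_tac_table(tacs)
  for (lab in c(config$aif_label, config$left_label, config$right_label))
    if (is.null(tacs[[lab]]))
      stop(sprintf("TAC input is missing the '%s' curve", lab), call. = FALSE)
  if (is.numeric(volumes)) {
    if (length(volumes) != 2)
      stop("'volumes' must name both kidneys: c(left_ml, right_ml)", call. = FALSE)
    volumes <- voi_volumes(volumes[1], volumes[2])
  }
  stopifnot(inherits(volumes, "voi_volumes"))
  gfr_res <- patlak_gfr(tacs[[config$aif_label]], tacs[[config$left_label]],
                        tacs[[config$right_label]], volumes,
                        window_end_min = config$window_end_min,
                        smooth = config$smooth,
                        floor_frac = config$floor_frac,
                        rise_frac = config$rise_frac,
                        extra_error_pct = config$gfr_extra_error_pct)
  erpf_res <- compute_erpf(tacs[[config$left_label]], tacs[[config$right_label]],
                           volumes, width_min = config$peak_width_min,
                           smooth = config$smooth,
                           rise_frac = config$rise_frac,
                           extra_error_pct = config$erpf_extra_error_pct)
  structure(list(gfr = gfr_res$gfr, erpf = erpf_res,
                 fit_left = gfr_res$fit_left, fit_right = gfr_res$fit_right,
                 peaks = gfr_res$peaks, volumes = volumes, config = config),
            class = "kidney_function_result")
}

#' @export
print.kidney_function_result <- function(x, ...) {
  print(x$gfr); print(x$erpf)
  invisible(x)
}

#' Flatten a subject result to a one-row data frame
#' @param x A [run_subject()] result.
#' @return One-row data frame with slopes, GFR, ERPF and errors.
#' @export
as_report_row <- function(x) {
  stopifnot(inherits(x, "kidney_function_result"))
  data.frame(K_left = x$gfr$K_left, K_right = x$gfr$K_right,
             gfr_left_ml_min = x$gfr$gfr_left_ml_min,
             gfr_right_ml_min = x$gfr$gfr_right_ml_min,
             gfr_total_ml_min = x$gfr$gfr_total_ml_min,
             gfr_error_ml_min = x$gfr$error_ml_min,
             erpf_total_ml_min = x$erpf$erpf_total_ml_min,
             erpf_error_ml_min = x$erpf$error_ml_min)
}

#' Cohort-level agreement with a reference method
#'
#' Matches subjects by `id` and runs [agreement_analysis()] for every
#' measure present in both tables, producing one row per comparison in the
#' layout mean +/- SD, r, Bland-Altman difference.
#'
#' @param fdg Data frame of PET-derived values: column `id` plus one column
#'   per measure (e.g. `gfr_total_ml_min`).
#' @param reference Data frame of reference values with the same column
#'   names.
#' @param measures Character vector of measure columns to compare; default
#'   all shared non-`id` columns.
#' @param diff_sign Bland-Altman sign convention (see
#'   [agreement_analysis()]).
#' @return Data frame with one row per measure: n, means and SDs of both
#'   methods, `pearson_r`, `p_value`, `paired_t_p`, `ba_mean_diff`,
#'   `ba_sd_diff`, limits.
#' @export
run_validation <- function(fdg, reference,
                           measures = NULL,
                           diff_sign = c("a_minus_b", "b_minus_a")) {
  diff_sign <- match.arg(diff_sign)
  if (!("id" %in% names(fdg)) || !("id" %in% names(reference)))
    stop("both tables need an 'id' column", call. = FALSE)
  ids <- intersect(fdg$id, reference$id)
  if (!length(ids)) stop("no matching subject ids", call. = FALSE)
  if (is.null(measures))
    measures <- setdiff(intersect(names(fdg), names(reference)), "id")
  if (!length(measures)) stop("no shared measure columns", call. = FALSE)
  f <- fdg[match(ids, fdg$id), , drop = FALSE]
  r <- reference[match(ids, reference$id), , drop = FALSE]
  rows <- lapply(measures, function(m) {
    rep_ <- agreement_analysis(f[[m]], r[[m]], diff_sign = diff_sign)
    data.frame(measure = m, n = rep_$n,
               fdg_mean = mean(f[[m]]), fdg_sd = stats::sd(f[[m]]),
               ref_mean = mean(r[[m]]), ref_sd = stats::sd(r[[m]]),
               pearson_r = rep_$pearson_r, p_value = rep_$p_value,
               paired_t_p = rep_$paired_t_p,
               ba_mean_diff = rep_$ba_mean_diff, ba_sd_diff = rep_$ba_sd_diff,
               ba_lower = rep_$ba_limits[1], ba_upper = rep_$ba_limits[2])
  })
  do.call(rbind, rows)
}

#' Extract a mean TAC from a dynamic image and a VOI mask
#'
#' @param dyn_image 4D numeric array (x, y, z, frame), kBq/ml.
#' @param mask Logical or 0/1 3D array.
#' @param schema A [frame_schema()] matching the 4th dimension.
#' @param label VOI label for the resulting curve.
#' @return A [tac()] of the per-frame mean concentration over the mask.
#' @export
extract_tac <- function(dyn_image, mask, schema, label = "voi") {
  stopifnot(length(dim(dyn_image)) == 4)
  mask <- array(as.logical(mask), dim(dyn_image)[1:3])
  if (!any(mask)) stop("empty VOI mask", call. = FALSE)
  if (dim(dyn_image)[4] != n_frames(schema))
    stop("4th image dimension must match the frame schema", call. = FALSE)
  vals <- vapply(seq_len(dim(dyn_image)[4]),
                 function(f) mean(dyn_image[, , , f][mask]), numeric(1))
  tac(schema, vals, label = label)
}
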