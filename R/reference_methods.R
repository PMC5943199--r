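#' CKD-EPI (2009) estimated GFR from serum creatinine
#'
#' The 2009 creatinine equation:
#' \deqn{eGFR = 141 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot
#'   \max(Scr/\kappa, 1)^{-1.209} \cdot 0.993^{age} \cdot 1.018[female]
#'   \cdot 1.159[black]}
#' with kappa = 0.7 (female) / 0.9 (male) and alpha = -0.329 (female) /
#' -0.411 (male). The result is in ml/min/1.73 m2; when height and weight
#' are supplied the value is de-indexed to absolute ml/min via the DuBois
#' body-surface area, so it is comparable with an absolute PET-derived GFR.
#'
#' @param age Age in years (> 0). Vectorized.
#' @param sex `"male"` or `"female"`.
#' @param creatinine_mg_dl Serum creatinine, mg/dl (> 0).
#' @param height_cm,weight_kg Optional; when both are given the indexed
#'   value is multiplied by BSA/1.73.
#' @param black Logical; apply the 2009 equation's race coefficient
#'   (default `FALSE`).
#' @return Estimated GFR in ml/min/1.73 m2, or absolute ml/min when
#'   de-indexed.
#' @export
ckd_epi_gfr <- function(age, sex, creatinine_mg_dl,
                        height_cm = NULL, weight_kg = NULL, black = FALSE) {
  n <- max(length(age), length(sex), length(creatinine_mg_dl))
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(as.character(sex), n)
  scr <- rep_len(as.numeric(creatinine_mg_dl), n)
  black <- rep_len(as.logical(black), n)
  if (anyNA(age) || anyNA(scr) || anyNA(sex))
    stop("age, sex and creatinine are required", call. = FALSE)
  if (any(age <= 0)) stop("age must be positive", call. = FALSE)
  if (any(scr <= 0)) stop("creatinine must be positive", call. = FALSE)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  ratio <- scr / kappa
  egfr <- 141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
  if (!is.null(height_cm) && !is.null(weight_kg)) {
    bsa <- dubois_bsa(rep_len(as.numeric(height_cm), n),
                      rep_len(as.numeric(weight_kg), n))
    egfr <- egfr * bsa / 1.73
  }
  egfr
}

#' DuBois body-surface area
#' @param height_cm Height in cm.
#' @param weight_kg Weight in kg.
#' @return BSA in m2.
#' @export
dubois_bsa <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive", call. = FALSE)
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Single-sample MAG3 plasma clearance
#'
#' One-compartment single-sample formalism: the apparent distribution volume
#' at the sampling time is V_app(t) = injected activity / plasma
#' concentration; under mono-exponential plasma kinetics with distribution
#' volume Vd,
#' \deqn{Cl = (V_d / t) \ln(V_{app}(t)/V_d).}
#' The assumed distribution volume is a configurable calibration constant
#' (default 6000 ml, a typical adult MAG3 distribution volume); alternative
#' single-sample calibrations can be emulated by swapping it.
#'
#' @param injected_activity_mbq Injected activity, MBq (> 0).
#' @param sample_time_min Blood-sampling time, minutes post-injection
#'   (> 0; the protocol draws at ~40 min).
#' @param plasma_kbq_ml Plasma activity concentration at the sampling time,
#'   kBq/ml (> 0), already corrected for any standard dilution.
#' @param assumed_vd_ml Assumed distribution volume, ml.
#' @return Plasma clearance in ml/min.
#' @export
mag3_clearance_single_sample <- function(injected_activity_mbq,
                                         sample_time_min,
                                         plasma_kbq_ml,
                                         assumed_vd_ml = 6000) {
  if (any(injected_activity_mbq <= 0)) stop("injected activity must be positive", call. = FALSE)
  if (any(sample_time_min <= 0)) stop("sample time must be positive", call. = FALSE)
  if (any(plasma_kbq_ml <= 0)) stop("plasma concentration must be positive", call. = FALSE)
  if (any(assumed_vd_ml <= 0)) stop("distribution volume must be positive", call. = FALSE)
  v_app <- injected_activity_mbq * 1000 / plasma_kbq_ml  # ml
  if (any(v_app <= assumed_vd_ml))
    stop("apparent distribution volume not above the assumed Vd; sample drawn too early or concentration too high",
         call. = FALSE)
  assumed_vd_ml / sample_time_min * log(v_app / assumed_vd_ml)
}

#' Convert MAG3 clearance to ERPF
#'
#' MAG3 is cleared by tubular extraction; its clearance (the tubular
#' extraction rate) underestimates effective renal plasma flow by the renal
#' extraction fraction, so
#' \deqn{ERPF = Cl_{MAG3} / E}
#' with E the extraction fraction (default 0.56, the conventional MAG3
#' value; configurable).
#'
#' @param clearance_ml_min MAG3 plasma clearance, ml/min (> 0).
#' @param extraction_fraction Renal extraction fraction in (0, 1].
#' @return ERPF in ml/min.
#' @export
erpf_from_mag3 <- function(clearance_ml_min, extraction_fraction = 0.56) {
  if (any(clearance_ml_min <= 0)) stop("clearance must be positive", call. = FALSE)
  if (any(extraction_fraction <= 0) || any(extraction_fraction > 1))
    stop("extraction fraction must be in (0, 1]", call. = FALSE)
  clearance_ml_min / extraction_fraction
}
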