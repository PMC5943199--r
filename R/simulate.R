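# Tracer-kinetic simulator: gamma-variate aorta input functions, kidney TACs
# following an irreversible-trapping model with a vascular component, whole
# cohorts with known ground truth, and blurred 4D phantoms for the
# input-function spill-out correction.

# evaluate a function with a temporary RNG state, restoring the caller's
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# fine simulation grid in minutes (dt = 0.25 s)
fine_times <- function(schema, dt_min = 1 / 240) {
  seq(0, schema_span_min(schema), by = dt_min)
}

# average a fine-grid curve over each frame of a schema (mean of fine samples
# whose times fall inside the frame) -- emulates list-mode frame binning
frame_average <- function(t_min, v, schema) {
  starts <- schema$starts / 60
  ends <- frame_ends(schema) / 60
  vapply(seq_along(starts), function(i) {
    idx <- which(t_min >= starts[i] - 1e-12 & t_min <= ends[i] + 1e-12)
    mean(v[idx])
  }, numeric(1))
}

# causal convolution of x with kernel k on a uniform grid (unit-sum kernel)
conv_causal <- function(x, k) {
  p <- length(k)
  if (p == 1) return(x * k)
  xx <- c(rep(0, p - 1), x)
  y <- stats::filter(xx, k, method = "convolution", sides = 1)
  as.numeric(y[p:(p + length(x) - 1)])
}

# normalized gamma transit kernel with given mean and SD (minutes) on grid
# step dt; flow changes the dispersion, not the arrival delay
gamma_kernel <- function(mean_min, sd_min, dt_min) {
  if (sd_min <= dt_min / 2) return(1)  # effectively a pure delay too short to matter
  shape <- (mean_min / sd_min)^2
  scale <- mean_min / shape
  tmax <- mean_min + 10 * sd_min
  tk <- seq(0, tmax, by = dt_min)
  k <- stats::dgamma(tk, shape = shape, scale = scale)
  k / sum(k)
}

#' Simulate an aortic input function
#'
#' Gamma-variate bolus plus a slow mono-exponential recirculation tail,
#' averaged over each frame of the schema (not point-sampled), emulating a
#' first-pass aortic curve whose frame maximum is `amplitude`.
#'
#' @param schema A [frame_schema()]; default [default_frame_schema()].
#' @param peak_time_min Time of the bolus maximum, minutes (analytic mode of
#'   the gamma variate); default 0.5.
#' @param amplitude Frame maximum of the curve, kBq/ml; default 157.8, a
#'   typical aortic peak at a 3 MBq/kg injection.
#' @param tail_fraction Recirculation tail plateau as a fraction of the
#'   bolus maximum; default 0.08.
#' @param delay_min Bolus arrival delay, minutes; default 0.1.
#' @param shape Gamma-variate shape parameter alpha; default 3.
#' @param tail_halflife_min Half-life of the slow tail decay, minutes;
#'   default 8 (the distribution-phase decline of the blood pool).
#' @return A [tac()] labelled `"aorta"`, carrying the fine-grid curve as
#'   attribute `"fine"` (list with `t` minutes and `c` kBq/ml).
#' @export
simulate_aif <- function(schema = default_frame_schema(), peak_time_min = 0.5,
                         amplitude = 157.8, tail_fraction = 0.08,
                         delay_min = 0.1, shape = 3, tail_halflife_min = 8) {
  stopifnot(peak_time_min > delay_min, amplitude > 0, tail_fraction >= 0)
  t <- fine_times(schema)
  beta <- (peak_time_min - delay_min) / shape
  tt <- pmax(t - delay_min, 0)
  # gamma variate normalized to max 1 at its mode delay + shape*beta
  bolus <- (tt / (shape * beta))^shape * exp(shape - tt / beta)
  bolus[t <= delay_min] <- 0
  tail <- tail_fraction * (1 - exp(-tt / 0.4)) *
    exp(-log(2) * tt / tail_halflife_min)
  tail[t <= delay_min] <- 0
  cfine <- bolus + tail
  vals <- frame_average(t, cfine, schema)
  sc <- amplitude / max(vals)
  out <- tac(schema, sc * vals, label = "aorta", warn_clip = FALSE)
  attr(out, "fine") <- list(t = t, c = sc * cfine)
  out
}

#' Add Gaussian frame noise to a TAC
#'
#' Adds zero-mean Gaussian noise with SD `noise_sd * sqrt(5 / duration_s)`
#' per frame (so `noise_sd` is the SD of a 5-s frame, and longer frames are
#' proportionally quieter, matching the variance structure of frame
#' averaging). Negative results are clipped to zero. Any fine-grid
#' ground-truth attribute is dropped: the result models a measured curve.
#'
#' @param x A [tac()].
#' @param noise_sd Noise SD on 5-s frames, kBq/ml.
#' @param seed Optional integer seed (RNG state restored).
#' @return A noisy [tac()].
#' @export
add_frame_noise <- function(x, noise_sd, seed = NULL) {
  stopifnot(inherits(x, "tac"), noise_sd >= 0)
  gen <- function() stats::rnorm(length(x$values), 0,
                                 noise_sd * sqrt(5 / x$schema$durations))
  eps <- if (is.null(seed)) gen() else with_seed(seed, gen())
  tac(x$schema, x$values + eps, label = x$label, smoothed = FALSE,
      warn_clip = FALSE)
}

# fine-grid input curve for a tac: stored fine attribute if present, else
# linear interpolation of the frame values on the midpoint time base
aif_fine <- function(aif, dt_min = 1 / 240) {
  f <- attr(aif, "fine")
  if (!is.null(f)) return(f)
  t <- fine_times(aif$schema, dt_min)
  g <- tac_grid(aif)
  list(t = t, c = stats::approx(g$t, g$v, xout = t, rule = 2)$y)
}

#' Ground-truth kinetic parameters for a simulated kidney
#'
#' @param Ki Irreversible uptake constant, min^-1 (the Patlak target);
#'   `>= 0`.
#' @param vb Vascular volume fraction in `[0, 1]`.
#' @param flow_scale Flow parameter, ml/min; controls peak sharpness via the
#'   transit-kernel dispersion `45/flow_scale` minutes (SD; 2.7 s at 1000
#'   ml/min) around a fixed 0.15-min mean renal transit time.
#' @param volumes A [voi_volumes()].
#' @param loss_rate Optional downstream loss rate, min^-1, acting on the
#'   accumulated activity only after `trap_min`.
#' @param trap_min Trapping interval, minutes; the tracer is fully trapped
#'   before this time, so it must be at least 2 min for the Patlak window to
#'   see irreversible kinetics. Default 3.
#' @param ve Exchangeable (reversible) volume fraction in `[0, 1]`; models
#'   the slowly equilibrating parenchymal pool, which makes the Patlak curve
#'   approach its asymptote from below. Default 0.
#' @param k_ex Equilibration rate of the exchangeable pool, min^-1.
#' @param drain_frac Delayed-drainage amplitude as a fraction of Ki; models
#'   filtrate formed in parenchyma not covered by the VOI that drains into
#'   the covered renal pelvis after `drain_delay_min` of tubular transit.
#'   This is what makes the measured curve rise above the pure trapping
#'   line from about 3 min on (the pelvis-filling hump). Default 0.
#' @param drain_delay_min Tubular transit delay of the drainage inflow,
#'   minutes; default 3.
#' @return An object of class `kinetic_truth`.
#' @export
kinetic_truth <- function(Ki, vb, flow_scale = 1000,
                          volumes = voi_volumes(150, 150),
                          loss_rate = 0, trap_min = 3,
                          ve = 0, k_ex = 0.5,
                          drain_frac = 0, drain_delay_min = 3) {
  if (Ki < 0) stop("Ki must be non-negative", call. = FALSE)
  if (vb < 0 || vb > 1) stop("vb must be in [0, 1]", call. = FALSE)
  if (ve < 0 || ve > 1) stop("ve must be in [0, 1]", call. = FALSE)
  if (k_ex <= 0) stop("k_ex must be positive", call. = FALSE)
  if (flow_scale <= 0) stop("flow_scale must be positive", call. = FALSE)
  if (loss_rate < 0) stop("loss_rate must be non-negative", call. = FALSE)
  if (drain_frac < 0) stop("drain_frac must be non-negative", call. = FALSE)
  if (trap_min < 2)
    stop("trapping interval must be at least 2 min", call. = FALSE)
  if (drain_frac > 0 && drain_delay_min < 2)
    stop("drainage delay must be at least 2 min (it must not reach the Patlak window)",
         call. = FALSE)
  structure(list(Ki = Ki, vb = vb, flow_scale = flow_scale, volumes = volumes,
                 loss_rate = loss_rate, trap_min = trap_min,
                 ve = ve, k_ex = k_ex,
                 drain_frac = drain_frac, drain_delay_min = drain_delay_min),
            class = "kinetic_truth")
}

#' Simulate a kidney TAC from an input function and ground truth
#'
#' The noise-free kidney curve is
#' \deqn{C_k(t) = v_b C_p^{smeared}(t) + v_e C_e(t) + A(t)}
#' where the smeared input is the AIF convolved with a normalized gamma
#' transit kernel (mean 0.15 min, SD `45/flow_scale` minutes, so flow
#' sharpens the peak without shifting it); the exchangeable pool
#' equilibrates with it as `Ce'(t) = k_ex (Cp_smeared(t) - Ce(t))`; and the
#' accumulated activity follows `A'(t) = Ki Cp(t)` while the tracer is
#' trapped (`t <= trap_min`) and `A'(t) = Ki Cp(t) - loss_rate A(t)`
#' afterwards. A delayed-drainage term (see [kinetic_truth()]) adds
#' `drain_frac * Ki * Cp(t - drain_delay_min)` to the influx, so that with
#' downstream loss the curve shows the hump-then-decline seen in
#' total-kidney curves between 3 and 5 min. Frame values are frame averages
#' of the fine-grid solution;
#' optional Gaussian noise has SD proportional to 1/sqrt(frame duration)
#' (so `noise_sd` is the SD of a 5-s frame).
#'
#' @param aif Input [tac()], ideally from [simulate_aif()] (its fine grid is
#'   reused).
#' @param truth A [kinetic_truth()].
#' @param schema Frame schema for the output; default the AIF's.
#' @param noise_sd Gaussian noise SD on 5-s frames, kBq/ml; 0 disables
#'   noise.
#' @param seed Optional integer seed for the noise (RNG state is restored).
#' @param label VOI label of the output.
#' @return A [tac()] (negative noisy values clipped to 0).
#' @export
simulate_kidney_tac <- function(aif, truth, schema = aif$schema, noise_sd = 0,
                                seed = NULL, label = "kidney") {
  stopifnot(inherits(aif, "tac"), inherits(truth, "kinetic_truth"))
  fine <- aif_fine(aif)
  t <- fine$t; cp <- fine$c
  dt <- t[2] - t[1]
  k <- gamma_kernel(0.15, 45 / truth$flow_scale, dt)
  cps <- conv_causal(cp, k)
  n <- length(t)
  # accumulated (trapped) activity, plus delayed drainage into the pelvis
  A <- numeric(n)
  influx <- truth$Ki * cp
  if (truth$drain_frac > 0) {
    lag <- round(truth$drain_delay_min / dt)
    cp_lag <- c(rep(0, min(lag, n)), cp)[seq_len(n)]
    influx <- influx + truth$drain_frac * truth$Ki * cp_lag
  }
  decay <- exp(-truth$loss_rate * dt)
  for (i in 2:n) {
    inc <- 0.5 * (influx[i - 1] + influx[i]) * dt
    A[i] <- if (t[i] <= truth$trap_min || truth$loss_rate == 0)
      A[i - 1] + inc
    else
      A[i - 1] * decay + inc
  }
  ck <- truth$vb * cps + A
  if (truth$ve > 0) {
    ce <- numeric(n)
    ed <- exp(-truth$k_ex * dt)
    for (i in 2:n)  # exact step for piecewise-constant driving
      ce[i] <- ce[i - 1] * ed + 0.5 * (cps[i - 1] + cps[i]) * (1 - ed)
    ck <- ck + truth$ve * ce
  }
  vals <- frame_average(t, ck, schema)
  if (noise_sd > 0) {
    gen <- function() stats::rnorm(length(vals), 0,
                                   noise_sd * sqrt(5 / schema$durations))
    eps <- if (is.null(seed)) gen() else with_seed(seed, gen())
    vals <- vals + eps
  }
  tac(schema, vals, label = label, warn_clip = FALSE)
}

#' Simulate a cohort of subjects with known kidney function
#'
#' Samples per-subject kinetic parameters from uniform ranges, generates an
#' aortic input function and two noisy kidney TACs per subject, and returns
#' the subjects together with a ground-truth table
#' (`gfr_truth = Ki * (V_left + V_right)`). Regenerating with the same seed
#' is bit-identical; the caller's RNG state is untouched.
#'
#' The default ranges emulate healthy adults under a 30-min dynamic renal
#' protocol: Ki 0.3-0.5 min^-1 and single-kidney volumes 120-180 ml (total
#' GFR roughly 80-170 ml/min), vascular fraction 0.30-0.45 (renal
#' parenchyma is strongly perfused, so the vascular flush dominates the TAC
#' peak), an exchangeable pool of 0.05-0.15 equilibrating at 1-2 min^-1, flow parameter 600-1400 ml/min, downstream loss 0.05-0.20
#' min^-1 beginning at 3 min, aortic peaks of 120-190 kBq/ml at 0.4-0.7
#' min, and 2 kBq/ml frame noise on 5-s frames.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed.
#' @param ranges Named list overriding any of the default parameter ranges
#'   (`ki`, `vb`, `flow`, `vol`, `loss`, `amp`, `peak_time`, `tail`, `ve`,
#'   `k_ex`, `drain`, `drain_delay`), each a
#'   length-2 `c(min, max)`.
#' @param noise_sd Frame-noise SD on 5-s frames, kBq/ml; default 2.
#' @param schema Frame schema; default [default_frame_schema()].
#' @return A list of class `synthetic_cohort`: `subjects` (list; each has
#'   `truth`, `aif`, `left_tac`, `right_tac`, `noise_seed`) and `truth`
#'   (data frame with the sampled parameters and `gfr_truth`).
#' @export
simulate_cohort <- function(n, seed = 1, ranges = list(), noise_sd = 2,
                            schema = default_frame_schema()) {
  stopifnot(n >= 1)
  rg <- list(ki = c(0.3, 0.5), vb = c(0.35, 0.50), flow = c(600, 1400),
             vol = c(120, 180), loss = c(0.12, 0.25), amp = c(120, 190),
             peak_time = c(0.4, 0.7), tail = c(0.05, 0.10),
             ve = c(0.08, 0.18), k_ex = c(1, 2),
             drain = c(0.15, 0.30), drain_delay = c(2.8, 3.5))
  rg[names(ranges)] <- ranges
  ru <- function(r) stats::runif(1, r[1], r[2])
  with_seed(seed, {
    subjects <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ki <- ru(rg$ki); vb <- ru(rg$vb); flow <- ru(rg$flow)
      vl <- ru(rg$vol); vr <- ru(rg$vol); loss <- ru(rg$loss)
      amp <- ru(rg$amp); pt <- ru(rg$peak_time); tail_fr <- ru(rg$tail)
      ve <- ru(rg$ve); k_ex <- ru(rg$k_ex)
      drain <- ru(rg$drain); drain_delay <- ru(rg$drain_delay)
      noise_seed <- sample.int(2^30, 1)
      truth <- kinetic_truth(ki, vb, flow_scale = flow,
                             volumes = voi_volumes(vl, vr), loss_rate = loss,
                             ve = ve, k_ex = k_ex,
                             drain_frac = drain, drain_delay_min = drain_delay)
      aif_true <- simulate_aif(schema, peak_time_min = pt, amplitude = amp,
                               tail_fraction = tail_fr)
      left <- simulate_kidney_tac(aif_true, truth, noise_sd = noise_sd,
                                  seed = noise_seed, label = "left_kidney")
      right <- simulate_kidney_tac(aif_true, truth, noise_sd = noise_sd,
                                   seed = noise_seed + 1L, label = "right_kidney")
      # the measured aorta curve carries the same frame noise as the kidneys
      aif <- add_frame_noise(aif_true, noise_sd, seed = noise_seed + 2L)
      subjects[[i]] <- list(id = i, truth = truth, aif = aif,
                            aif_true = aif_true, left_tac = left,
                            right_tac = right, noise_seed = noise_seed)
      rows[[i]] <- data.frame(id = i, Ki = ki, vb = vb, ve = ve, k_ex = k_ex,
                              drain_frac = drain,
                              drain_delay_min = drain_delay,
                              flow_scale = flow,
                              vol_left_ml = vl, vol_right_ml = vr,
                              loss_rate = loss, aif_amplitude = amp,
                              aif_peak_time_min = pt,
                              gfr_truth = ki * (vl + vr),
                              noise_seed = noise_seed)
    }
    structure(list(subjects = subjects, truth = do.call(rbind, rows)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects, true GFR %.0f-%.0f ml/min\n",
              nrow(x$truth), min(x$truth$gfr_truth), max(x$truth$gfr_truth)))
  invisible(x)
}
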