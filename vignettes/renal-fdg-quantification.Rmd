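---
title: "Quantifying renal function from dynamic FDG-PET: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying renal function from dynamic FDG-PET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalpet)
```

## The measurement problem

A dynamic FDG-PET acquisition over the abdomen yields, after VOI
averaging, time-activity curves (TACs, kBq/ml) for the descending aorta
and for each kidney. Two functional parameters are extracted from those
curves alone, with no multi-compartment fitting:

* **GFR** from the Patlak graphical analysis of each kidney against the
  aortic input function (AIF), and
* **ERPF** from the kidney TAC peak itself.

Both estimators multiply a rate (min⁻¹) by the kidney VOI volume (ml) and
sum the two kidneys, so the outputs are absolute ml/min and single-kidney
values come for free.

## Time base and frame schema

The default acquisition re-binning is 60 frames of 5 s followed by 25
frames of 60 s (85 frames, 30 min). All estimators work on the
frame-midpoint time base in minutes; midpoints are the natural abscissa
for frame-averaged data and make the trapezoidal curve integrals exact for
piecewise-linear curves. Outside the midpoint range the curve is extended
as a constant so that integrals may start at injection (`t = 0`): for the
constant-input closed form this extension is what makes
`∫₀ᵗ C_p = c·t` hold exactly.

## Smoothing

Early 5-s frames are noisy; the package smooths each TAC with a
sliding-window Bézier filter: around every frame a quadratic Bézier
segment (Bernstein basis, which spans the quadratic polynomials) is
least-squares fitted to the five neighbouring frame points on the midpoint
time base and evaluated at the central frame time. Consequences used by
the tests: constants, lines and parabolas are reproduced exactly (so the
filter is idempotent on them and a linear ramp stays monotone), endpoints
are preserved exactly (the three-point boundary windows interpolate),
alternating noise loses total variation, and peak locations move at most
one frame. An interpolating spline through the frame points would have
been the identity on this time base, which is why the filter fits rather
than interpolates.

## Peak detection

The vascular flush is the global maximum within the first 5 min of the
smoothed curve. The peak *rise* is the last frame before the maximum whose
baseline-corrected value is at or below 5% of the baseline-corrected
maximum (baseline = curve minimum before the peak). The 5% convention is a
package choice; it is exposed as `rise_frac`. Degenerate curves (all zero,
constant, maximum in the first frame) are rejected with errors rather than
guessed at.

## Patlak GFR

For an irreversibly trapped tracer, `C_k/C_p` against `x = ∫C_p/C_p` is
asymptotically linear with slope `K`, the net uptake constant. Design
choices, all surfaced as arguments with these defaults:

* **Fit window** (`window_end_min = 2`): from the point whose frame is the
  kidney-TAC peak maximum through the last point at or before 2 min
  post-injection, measured in scan time, not Patlak-x. At least 3 points
  are required.
* **Input floor** (`floor_frac = 0.01`): frames with `C_p` below 1% of the
  AIF maximum are excluded from the transform to avoid division blow-ups
  before bolus arrival.
* **Whole-blood input**: the aorta curve is used as measured; no
  hematocrit conversion to plasma concentration is applied.
* **Negative slopes** are reported with a warning, never clamped: a
  negative `K` is a diagnostic signal.
* **Slope uncertainty**: smoothing correlates neighbouring frames, which
  makes the ordinary least-squares slope error of the smoothed fit
  optimistic; `patlak_gfr()` therefore reports the larger of the
  smoothed-fit and raw-point-fit standard errors over the same window.
  Even so, the short peak-anchored window carries a parameter-dependent
  systematic bias (the vascular/exchange transient right after the peak)
  on the order of a few percent that a single-realization fit error
  cannot represent; the fit error should be read as a noise floor, not a
  total uncertainty. The GFR error combines the slope errors (scaled by
  volume) with a 7% VOI-reproducibility term by root-sum-square.

## ERPF from the peak

Per kidney, `ratio = P_max / ∫ TAC` over the window from the peak rise to
1 min after the rise (`width_min = 1`), on the same smoothed curve that
supplied `P_max`. The ratio's units are min⁻¹ and any common amplitude
factor cancels, so the estimator is exactly scale invariant and never
reads the AIF. For a rectangular pulse fully inside the window the ratio
is exactly 1/width — the sanity anchor used in the tests.

## Input-function spill-out correction

PET blurring spreads aortic activity beyond the vessel wall,
underestimating the measured AIF, most severely at the early peak. The
correction measures, per frame, the mean concentration `C_T` over the
*total* region (apparent blurred aorta = spill-out region, segmented by
threshold from the summed early frames, frames 2–7 by default, plus its
background shell) and `C_B` over the shell alone, then solves the activity
balance `C_T V_T = C_A V_A + C_B V_B` for the true aortic concentration
`C_A`. The shell is the radial dilation of the spill-out mask by 3 voxels
(12 mm at 4 mm voxels), implemented as morphological dilation with a
Euclidean ball — identical to thresholding a Euclidean distance transform.
The segmentation threshold (default 10% of the summed-image maximum) is a
package choice; lowering it toward zero captures the full blur support,
which is what makes the phantom recovery exact. Negative corrected values
are clipped to zero with a warning.

## The synthetic-data generator

Every estimator is validated against simulated data with known ground
truth, because per-subject clinical TACs are not distributable. The
generator emulates:

* an **AIF** as a gamma-variate bolus (shape 3, arrival delay 0.1 min,
  default mode 0.5 min, default frame maximum 157.8 kBq/ml — a typical
  aortic peak at ~3 MBq/kg) plus a recirculation tail of 5–10% of the peak
  decaying with an 8-min half-life (the distribution-phase decline of the
  blood pool);
* a **kidney** as `C_k = v_b·C_p^sm + v_e·C_e + A`, where `C_p^sm` is the
  AIF convolved with a gamma transit kernel of fixed mean 0.15 min — the
  scale of renal vascular transit — and dispersion SD `45/flow_scale` min,
  so the flow dial sharpens the peak without shifting its arrival (the
  property that makes the ERPF estimator strictly monotone in flow);
  `C_e` is a parenchymal pool equilibrating at `k_ex`; `A` accumulates at
  `Ki·C_p`, fully trapped before `trap_min = 3` min and subject to a
  downstream loss rate afterwards, plus a delayed drainage inflow
  `drain_frac·Ki·C_p(t − delay)` representing filtrate formed in
  parenchyma the VOI does not cover that drains into the covered pelvis.
  Loss and drainage together shape the characteristic hump-then-decline
  of total-kidney curves between 3 and 5 min;
* **noise** as zero-mean Gaussian with SD `noise_sd·sqrt(5 s/duration)` —
  the variance structure of frame averaging — applied to kidney *and*
  aorta curves (default 2 kBq/ml on 5-s frames), with physical clipping at
  zero;
* **4D phantoms**: a cylindrical aorta painted with the AIF and convolved
  with an activity-conserving truncated-Gaussian PSF, for the spill-out
  correction.

Cohort defaults (all overridable through `ranges`): `Ki` 0.3–0.5 min⁻¹
and single-kidney volumes 120–180 ml, giving true GFR roughly in the
healthy 80–170 ml/min band; `v_b` 0.35–0.50 plus `v_e` 0.08–0.18 at
`k_ex` 1–2 min⁻¹, so the flush dominates the curve and the apparent
Patlak intercept lands near the ~0.5 values seen in practice; flow
600–1400 ml/min; loss 0.12–0.25 min⁻¹ from 3 min with drainage 0.15–0.30
of `Ki` delayed 2.8–3.5 min (hand-drawn VOIs plausibly miss 13–23% of
parenchyma). These were chosen once, on physiological grounds, and the
corner combinations were checked to keep the flush peak dominant — the
regime in which peak-anchored fitting is defined.

What the generator does **not** emulate: reconstruction artifacts and
spatially correlated (non-Gaussian) noise, respiratory motion, true
multi-exponential FDG blood clearance, pathology (obstruction, diabetes,
chronic kidney disease), and any calibrated link between the ERPF ratio
and physiological plasma flow — for the latter only monotonicity in the
flow dial is claimed. Passing recovery tests on this generator therefore
demonstrates internal consistency of the estimators under realistic noise
and kinetics, not clinical accuracy.

## Numerical choices

Fine-grid simulation step 0.25 s; curve integrals are exact trapezoids of
the piecewise-linear midpoint representation; the accumulation ODE uses an
exponential-integrator step (exact for piecewise-constant influx and
loss); convolutions are causal FIR filters with unit-sum kernels; the
random-number state of the caller is always saved and restored, and
cohorts regenerate bit-identically from their seed. Problem sizes in the
test and acceptance runs (200-subject cohorts, 32×32×24 phantom grids,
10⁵-point oracle grids) were picked so the whole validation executes in a
few minutes on one core while leaving the stochastic criteria comfortable
margins.

## Window sensitivity: a known, documented divergence

Extending the Patlak window from 2 to 4 min on the simulated cohorts
*lowers* the mean GFR (the acceptance run reports the signed difference):
after 3 min the downstream loss pulls the late Patlak points below the
trapping asymptote, and within any irreversible-trapping model with
downstream loss that is the only possible direction, because a closed VOI
whose influx is `Ki·C_p` can never rise above the trapping line faster
than the delayed-drainage inflow allows. On real kidneys the opposite has
been reported — later windows give *larger* GFR — which implies late-time
behaviour (strong blood-pool decay combined with retained tissue
activity) outside this model family. The delayed-drainage term moves the
simulated curves in the right direction, but a magnitude large enough to
flip the sign would require the VOI to miss nearly half the parenchyma,
which we consider implausible and did not adopt. Users comparing window
settings on real data should expect the 2-min window to be the
conservative choice.

## Reference methods

* **CKD-EPI (2009)** creatinine equation, sex-specific `κ` and `α`,
  optional race coefficient, result in ml/min/1.73 m²; when height and
  weight are available the value is de-indexed to absolute ml/min with
  the DuBois body-surface area so it is commensurable with the
  PET-derived GFR.
* **Single-sample MAG3 clearance** via the one-compartment
  apparent-distribution-volume formalism `Cl = (V_d/t)·ln(V_app/V_d)` with
  `V_app = dose/concentration` and a configurable assumed `V_d`
  (default 6000 ml); **ERPF** is the clearance divided by the MAG3
  extraction fraction (default 0.56). Both constants are deliberate,
  documented package defaults that can be swapped for any other
  single-sample calibration.

## Statistics

Agreement between two methods is summarized by the Pearson correlation
with its two-sided p-value, a paired t test, and Bland–Altman mean
difference with ±2 SD limits (the sign convention is an argument). The
normality screen is a one-sample Kolmogorov–Smirnov test against a normal
with the sample's own mean and SD; estimating the parameters from the same
sample makes the p-value conservative (the Lilliefors caveat), which is
acceptable for a screen. Error budgets combine components by
root-sum-square; percent components are converted to absolute on the
subject's value first.

## Known limitations

The Patlak slope from the short peak-anchored window carries a small
systematic bias from the vascular transient at the anchor; the reported
fit error does not cover it (see above). Cortex-only analyses reuse the
same code paths but inherit larger VOI reproducibility errors. The
activity-balance correction assumes all spill-out activity stays inside
the segmented spill-out region and that the background shell is
representative; both fail under heavy motion. The single-sample MAG3
formalism is only as good as the assumed distribution volume.
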