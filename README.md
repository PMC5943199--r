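# renalpet

Kidney function from a single dynamic FDG-PET scan: **renalpet** estimates
the glomerular filtration rate (GFR) and the effective renal plasma flow
(ERPF) of each kidney from time-activity curves (TACs) of the aorta and the
kidneys, so that a routine 30-minute dynamic scan can double as a renal
function test. It is written for imaging scientists and nuclear-medicine
physicists who have per-VOI TACs (or 4D volumes plus masks) and kidney VOI
volumes, and who want method-level building blocks rather than a black box.

## The estimators

**GFR.** FDG filtered by the glomeruli is effectively trapped in the kidney
during the first minutes, so the tissue curve obeys the irreversible-uptake
(Patlak) relation

    C_k(t) / C_p(t) = K * (∫₀ᵗ C_p dτ) / C_p(t) + V₀

where `C_p` is the aortic input function. Plotting `y = C_k/C_p` against
`x = ∫C_p/C_p` linearizes the kinetics; the slope `K` (min⁻¹) is the net
uptake constant. The fit window runs from the point corresponding to the
kidney TAC peak maximum to the last point at or before 2 min
post-injection, and

    GFR [ml/min] = K_right · V_right + K_left · V_left

with `V` the kidney VOI volumes in ml.

**ERPF.** The TAC peak integral (from the peak rise to 1 min after the
rise) represents the initial blood flush, and the peak maximum `P_max` the
largest fluid quantity the kidney can hold at once; their ratio is a rate
(min⁻¹) describing how fast the kidney turns over that maximal amount:

    ERPF [ml/min] = (P_max / ∫_peak TAC)_right · V_right
                  + (P_max / ∫_peak TAC)_left  · V_left

The amplitude cancels in the ratio, so the estimator is scale invariant and
independent of the input function.

Around these two estimators the package provides: Bézier-type TAC smoothing
(sliding-window least-squares Bernstein fits), peak detection, an
activity-balance partial-volume correction of the aortic input function
(`C_T V_T = C_A V_A + C_B V_B`, solved for `C_A` per frame), CKD-EPI and
single-sample MAG3 reference calculators, agreement statistics (Pearson,
paired t, Bland–Altman, KS normality screen, root-sum-square error
budgets), and a tracer-kinetic simulator that generates aorta and kidney
curves, whole cohorts with known ground truth, and blurred 4D phantoms.

## Worked example

```r
library(renalpet)

co  <- simulate_cohort(1, seed = 42)     # one synthetic subject
s   <- co$subjects[[1]]
res <- run_subject(list(aorta = s$aif, left_kidney = s$left_tac,
                        right_kidney = s$right_tac),
                   s$truth$volumes)
res
#> GFR: 160.2 ml/min (left 81.7 + right 78.4), error 12.3 ml/min
#> ERPF: 488 ml/min (left 250 + right 237), error 34 ml/min
res$fit_left
#> Patlak fit: K = 0.4814 min^-1 (SE 0.021), intercept = 1.05, r^2 = 0.973, 17 points
co$truth$gfr_truth
#> [1] 158.6383
```

The subject was generated with a true uptake constant `Ki = 0.483 min⁻¹`
(true GFR 158.6 ml/min); the peak-anchored 2-min Patlak fit recovers
`K = 0.481 min⁻¹` per kidney and a total GFR of 160.2 ml/min. The reported
error combines the slope standard error (scaled by volume) with a 7%
VOI-reproducibility term by root-sum-square. The ERPF of 488 ml/min is the
peak-ratio estimate times volume, summed over kidneys; its accuracy is
bounded by the estimator definition, not by the input function, which it
never reads.

A command-line front end with the same functionality lives in
`inst/cli/renalpet.R` (`simulate`, `gfr`, `erpf`, `correct-aif`,
`reference`, `validate` subcommands).

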