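---
title: "Kinetic quantification of dynamic spinal PET with an image-derived input function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic quantification of dynamic spinal PET with an image-derived input function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petkin)
```

## The problem

Activated glia overexpress the 18 kDa translocator protein (TSPO), so a
dynamic PET scan with a TSPO radioligand such as [11C]DPA713 can quantify
neuroinflammation in vivo. In small spinal structures — the cervical
neuroforamina and the spinal cord — this is demanding: regions are small and
noisy, arterial cannulation is undesirable, and the 20-minute half-life of
carbon-11 limits the usable scan to about an hour. `petkin` implements the
full quantification chain for this setting:

1. an **image-derived input function** (IDIF) built from an ascending-aorta
   blood-pool curve plus a handful of venous samples,
2. **compartmental models** (one-tissue reversible `1T2k`, two-tissue
   irreversible `2T3k`, two-tissue reversible `2T4k`, each with a fractional
   blood-volume term),
3. **linearized** (Logan, Patlak) and **simplified static** (SUV, TBR)
   measures,
4. **model selection and quality control** (Akaike preference, VT-outlier
   rule, motion-artifact detection), and
5. **test-retest reliability** statistics (ICC(2,1), SEM, SDD, Bland-Altman
   limits of agreement).

Because no patient data ship with the package, a synthetic-subject generator
with known ground truth drives every test.

## Models

### Compartment models

With metabolite-corrected plasma concentration $C_p(t)$ and whole-blood
concentration $C_{wb}(t)$, the measured regional concentration is

$$C_{PET}(t) = (1 - V_b)\, C_T(t) + V_b\, C_{wb}(t),$$

where $C_T = h \ast C_p$ and the impulse response $h$ is

- `1T2k`: $h(t) = K_1 e^{-k_2 t}$,
- two-tissue: $h(t) = \frac{K_1}{\alpha_2-\alpha_1}\left[(k_3+k_4-\alpha_1)
  e^{-\alpha_1 t} + (\alpha_2-k_3-k_4) e^{-\alpha_2 t}\right]$ with
  $\alpha_{1,2} = \tfrac12\left[(k_2+k_3+k_4) \mp
  \sqrt{(k_2+k_3+k_4)^2 - 4k_2k_4}\right]$; the irreversible `2T3k` model is
  the $k_4 = 0$ special case.

Macro-parameters: $V_T = K_1/k_2$ (`1T2k`), $V_T = (K_1/k_2)(1 + k_3/k_4)$
(`2T4k`), and $K_i = K_1 k_3/(k_2+k_3)$ (`2T3k`). Convolutions run on a
1-second grid (discretisation error well below 0.1% for these kinetics — the
test suite verifies agreement with a stiff ODE integrator to 0.1% of the
curve maximum), and model values are averaged over each frame rather than
evaluated at midpoints, because the 600-second late frames otherwise bias
the comparison with measured frame averages.

### Fitting

`fit_compartment_model()` minimises weighted least squares with weights
proportional to frame duration over activity (floor-clamped at 5% of the
peak, normalised to mean 1) — the usual count-statistics approximation.
Optimisation is bounded Levenberg-Marquardt (`minpack.lm::nls.lm`) with
three starts at 10/30/50% of the parameter boxes; for the two-tissue models
a fourth start is seeded from the one-tissue solution with $k_3 = 0$, which
reproduces the one-tissue impulse response exactly and therefore guarantees
the nested-model inequality (fitted `2T4k` RSS never exceeds fitted `1T2k`
RSS).

Parameter boundaries follow physiological limits: all lower bounds 0,
$K_1 \le 0.7$ mL·cm⁻³·min⁻¹, $k_3 \le 0.8$ min⁻¹, $V_b \le 0.7$, and
$V_T \le 40$. The $V_T$ bound is enforced exactly for the one-tissue models
by reparameterising $k_2 = K_1/40 + s$ with $s \ge 0$; for `2T4k`, where the
bound couples all four rate constants, a smooth penalty residual activates
above $V_T = 40$ (zero below it, so unconstrained fits are untouched). These
bounds constrain *estimation* only; `forward_tac()` simulates any physically
valid parameter set (e.g. $V_b = 1$ reproduces the blood curve).

The model-comparison statistic is the Gaussian-residual Akaike information
criterion, $\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2p$, with $p$ counting
all fitted parameters including $V_b$ (3, 4 and 5 for `1T2k`, `2T3k`,
`2T4k`). Ties go to the model with fewer parameters.

### Input function

The IDIF follows a four-step procedure:

1. 1-3 exponential curves are fitted separately to the discrete whole-blood
   and plasma samples (order chosen by AIC; noiseless fits are protected
   against spurious extra terms by a relative RSS floor);
2. a Hill-type model $pf(t) = 1 - a\,t^b/(t^b + c^b)$ is fitted to the
   plasma parent fractions — $pf(0)=1$ by construction, monotone, with
   asymptote $1-a$;
3. the early (< 5 min) input shape is taken from the blood-pool image curve:
   a rise + multi-exponential model is fitted to the early frames *through
   the frame-averaging operator* (long frames otherwise flatten the bolus
   peak), then multiplied by a single constant scale factor so the curve
   meets the sample-fitted whole-blood activity exactly at 5 min; plasma is
   derived from the fitted plasma/whole-blood ratio and metabolite-corrected
   plasma as plasma × $pf$;
4. a per-region delay is estimated by grid search over ±30 s in 1-s steps,
   choosing the shift that minimises the one-tissue fit RSS.

On noiseless synthetic subjects the reconstruction is exact to numerical
precision; the packaged tests require < 3% RMS.

### Linearized and static measures

`logan_vt()` regresses $\int_0^t C_T/C_T(t)$ on $\int_0^t C_p/C_T(t)$ over
late frames and reports the slope as $V_T$; `patlak_ki()` regresses
$C_T(t)/C_p(t)$ on $\int_0^t C_p/C_p(t)$ and reports the slope as $K_i$.
Points enter the regression when their frame midpoint lies at or beyond
$t^* = 30$ min. The 19-frame protocol leaves only two midpoints past 30 min,
so when fewer than three qualify the rule widens to every frame *extending*
beyond $t^*$; for one-tissue kinetics the Logan plot is exactly linear at
all times, so the widening does not bias that estimator. For slowly
equilibrating two-tissue kinetics Logan approaches $V_T$ from below and
needs a genuinely late $t^*$; the estimator checks therefore use finer late
framing and $t^* = 60$ min for that case.

`compute_suv()` is the interval mean activity normalised by injected dose
per body weight (density 1 g/mL, so SUV $= \bar{C}\,[\mathrm{kBq/mL}] \cdot
\mathrm{weight\,[kg]} / \mathrm{dose\,[MBq]}$); `compute_tbr()` divides the
interval-mean tissue activity by the interval mean of the fitted whole-blood
(TBR-WB) or metabolite-corrected plasma (TBR-PP) curve — ratios of interval
means, not means of instantaneous ratios, and fitted curves rather than raw
samples because the venous draws are sparse inside the 20-50 and 30-60 min
windows.

### Quality control

A fit is flagged by `flag_vt_outlier()` when its $V_T$ exceeds 1.5× the
group median for the same region (strict, one-sided). `detect_motion()`
flags late frames (midpoint > 10 min) that drop more than 30% from the
previous frame while the next frame recovers by more than 15%, or any
sustained late drop above 40%; smooth decaying TACs at 3% frame noise stay
below a 5% false-positive rate. Records without blood or blood-pool data are
excluded with reason `missing_input` — mirroring the scenario where the
aorta leaves the field of view.

### Reliability statistics

`icc_2_1()` computes the single-measures absolute-agreement intraclass
correlation from the two-way ANOVA mean squares,
$(MS_R - MS_E)/(MS_R + MS_E + \tfrac{2}{n}(MS_C - MS_E))$ for two sessions,
with the McGraw-Wong F-based 95% CI. The same mean-squares value serves the
"two-way random" and "two-way mixed" absolute-agreement single-measures
labels, which coincide numerically. SEM is $sd\sqrt{1-\mathrm{ICC}}$ — the
radical is deliberate: with SEM 2.02, $2.02 \times 1.96 \times \sqrt 2 =
5.60$ matches the companion SDD value, while $2.02 \times 2 \times 1.96$
does not — and SDD $= \mathrm{SEM} \times 1.96\sqrt 2$. Which SD feeds the
SEM is an explicit argument (`sem_sdd(sd, icc)`); the pipeline uses the
pooled test/retest SD. Bland-Altman differences are retest − test with
limits $\bar d \pm 1.96\,sd(d)$ ($n-1$ SD). `correlate()` picks Pearson when
both variables pass Shapiro-Wilk at $\alpha = 0.05$, Spearman otherwise, and
categorises $r$ as low (< 0.30), moderate [0.30, 0.45), substantial
[0.45, 0.60) or high (≥ 0.60); ICC bands are poor (≤ 0.40), fair-to-good
(0.41-0.75) and good-to-excellent (≥ 0.76), with 0.76 the default
pass threshold (`run_config(reliability_threshold = )`).

## The synthetic generator

`generate_cohort()` emulates the study conditions:

- **Frame schedule**: the 19-frame acquisition protocol (1×15, 3×5, 3×10, 4×60,
  2×150, 2×60, 4×600 s). Its durations sum to 52 min while the scan is
  described as 60 min; the generator default extends the final frame to
  close the 60-min span (`frame_schedule(extend_last = TRUE)`) so that
  30-60 min windows and the 59-min venous draw are defined. The verbatim
  verbatim protocol schedule remains available as `frame_schedule()`.
- **Whole blood**: linear rise from injection to a peak at 0.75 min, then a
  tri-exponential decay (fractions 0.75/0.20/0.05 at rates 3.5/0.30/0.010
  min⁻¹) — a standard shape for a 20-s [11C] bolus. The amplitude, 5.5 SUV
  at the peak, was calibrated once so that the default cohort's
  neuroforaminal target SUV(30-60) lands near the reference group mean
  (≈ 1.8) under the reference VT moments; per-subject lognormal jitter
  (10%) adds biological variation. Plasma is 0.8 × whole blood.
- **Parent fraction**: the Hill model with $a = 0.35$, $b = \log 3/\log 2$,
  $c = 30 (3/4)^{1/b} \approx 25$ min, chosen in closed form so that
  $pf(30) = 0.80$ and $pf(60) = 0.72$ exactly; small per-session jitter on
  $a$ (SD 0.01) mimics the metabolite-determination variability seen between
  sessions.
- **Kinetics**: per region, VT is drawn either uniformly from `vt_range`
  (default 7-17) or from a truncated normal matching reference
  target/unaffected moments (`default_region_table()`); $K_1 \sim
  U(0.15, 0.45)$, $V_b \sim U(0.03, 0.08)$, and $k_2$ is solved from VT.
  All true parameters respect the fitting bounds.
- **Noise**: additive zero-mean Gaussian per frame with SD ∝
  $\sqrt{\mathrm{activity}/\mathrm{duration}}$, normalised so the last
  frame's CV equals `noise_cv` (default 3%). Because the last frame is long
  and low-activity, early 5-second frames are far noisier — as in real
  data — and the fitting weights downweight them accordingly. Negative
  values are clamped at zero.
- **Test-retest**: retest sessions multiply true $K_1$ and VT by lognormal
  factors with log-SD `retest_log_sd` (default 0.1), redraw the blood
  amplitude and parent-fraction jitter, and re-noise the TACs.
- **Motion**: with probability `motion_probability` a TAC receives a
  single-frame drop of 35-60% at a random late frame
  (`add_motion_artifact()`).

What the generator does **not** emulate: voxel-level image formation,
partial-volume and spill-over effects, attenuation/scatter residuals,
inter-frame registration errors, and TSPO-genotype affinity differences.
Tests passing on this generator therefore demonstrate correctness of the
estimators under the stated noise model, not robustness to every artifact of
real scans.

## Numerical choices

- 1-second evaluation grid for all convolutions and integrals; trapezoid
  quadrature; frame averages via a precomputed weight matrix.
- Exponential convolution by an exact recursive filter (linear cost, no
  FFT edge effects).
- Multi-exponential sample fits floor the RSS at $(10^{-6} \max y)^2 n$
  when comparing AIC across orders, so noiseless data do not select
  spurious extra terms on log(0).
- Delay search is bounded to ±30 s (venous-to-aorta and transit offsets are
  well inside this for a thoracic field of view) with 1-s resolution.
- Degenerate inputs fail loudly: all-zero TACs, inputs shorter than the
  schedule, zero junction activity, constant series in `correlate()`.
- Monte-Carlo checks of estimator recovery (e.g. ICC at $n = 500$) average
  over replicate cohorts so that the check measures estimator bias rather
  than single-draw sampling noise.

## Problem sizes used in the packaged checks

The packaged tests and the acceptance script run the complete chain at
cohort sizes chosen to keep Monte-Carlo error well inside the stated
tolerances: 50 subjects for VT recovery, 100 for the Logan/compartmental
correlation and the model-preference tally, 400 clean TACs for the
motion-detector false-positive rate, 500 subjects × 20 replicates for ICC
recovery, and 20 random parameter draws for the ODE-oracle comparison.
Cohort correlations are computed after the VT-median outlier exclusion, in
the same order QC precedes statistics in `run_pipeline()` — with only three
usable late frames the Logan regression occasionally produces a wild slope
on a noisy TAC, and the outlier rule exists precisely to catch those. The paired-difference and reliability arithmetic reuse the
reference group moments (n = 14 analysable subjects, n = 6 test-retest) as
generator inputs.

## Known limitations

- The 2T4k $V_T \le 40$ bound is a smooth penalty, not a hard box; fits
  that would exceed it converge to just above the boundary rather than
  exactly on it.
- Logan estimates carry the well-known noise-dependent negative bias (the
  test suite demonstrates it); no multilinear reformulation is provided.
- The delay estimator assumes the one-tissue model describes the early
  kinetics well enough to rank shifts; gross model violation would bias it.
- Reference-tissue models are deliberately absent: unaffected spinal tissue
  still binds the tracer specifically, so no valid reference region exists
  in this application.
- `1T2k_WB` (metabolite correction omitted) defaults to uncorrected plasma
  as the input; whole blood is available via `wb_input = TRUE`. The choice
  matters little for ranking subjects — with a shared parent-fraction curve
  the variant's VT is a monotone transform of the corrected VT.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(
  generator = generator_config(n_subjects = 14,
                               regions = default_region_table(),
                               test_retest = TRUE, seed = 1),
  models = c("1T2k", "2T3k", "2T4k"))
res <- run_pipeline(cfg)
res$table_regions      # target vs unaffected, per metric and region
res$table_reliability  # ICC, SEM, SDD, limits of agreement per metric
res$preference         # AIC model-preference tally
write_reports(res, "reports")
```
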