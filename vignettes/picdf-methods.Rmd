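---
title: "Estimating persistent-inward-current activity from paired motor-unit discharge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating persistent-inward-current activity from paired motor-unit discharge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picdf)
library(dplyr)
```

## The scientific problem

Motoneurons do not relay synaptic drive passively: dendritic persistent
inward currents (PICs), facilitated by serotonergic and noradrenergic input,
amplify and prolong discharge for a given drive. The strength of this
intrinsic amplification cannot be measured directly in humans, but it leaves
two fingerprints in the discharge of motor units decomposed from high-density
surface EMG during slow triangular torque ramps:

* **ΔF (delta frequency)** — recruitment–derecruitment hysteresis. A
  higher-threshold *test* unit is recruited at some drive level and, if PICs
  keep its motoneuron depolarized, derecruited at a lower one. Drive itself is
  unobservable, so a lower-threshold *control* unit's smoothed discharge rate
  is used as its proxy: ΔF is the control rate at the test unit's
  recruitment minus the control rate at its derecruitment, in pulses per
  second (pps).
* **Brace height** — the deviation of the ascending discharge-rate-versus-
  torque trajectory from a straight line between recruitment and peak
  discharge, normalized to the hypotenuse of the right triangle formed by
  those two points (%rTri). It indexes the nonlinear acceleration of
  discharge attributed to neuromodulatory amplification.

`picdf` implements the full analysis chain for these quantities —
decomposed spike trains in, cohort-level robust statistics out — together
with a motoneuron-pool simulator whose injected hysteresis has a closed-form
ΔF, so every estimator in the chain can be validated against known ground
truth.

## The discharge model behind the simulator

The simulator is intentionally the simplest model with an analytic ΔF
oracle, because its job is to validate the *estimator*, not to model
motoneuron biophysics. A common drive $D(t)$ (in %MVT) follows the
triangular torque target (10 s up, 10 s down; ramp rates of 2, 4 and
6 %MVT·s⁻¹ for ramps peaking at 20, 40 and 60 %MVT). Unit $i$ has a
recruitment threshold $\theta_i$ and begins firing when $D(t) \ge \theta_i$;
from its first spike onward its *effective* threshold drops by the
hysteresis parameter $\Delta\theta_i \ge 0$ — the PIC-like ingredient — and
its instantaneous rate is

$$r_i(t) = \min\{r_\min + g_i\,[D(t) - (\theta_i - \Delta\theta_i)],\; r_{sat}\}$$

until $D(t) < \theta_i - \Delta\theta_i$. Spike times are drawn by
integrating $r_i$ and placing spikes at unit increments of the integral,
each increment jittered multiplicatively by a log-normal factor with
coefficient of variation `isi_cv` (log-normal keeps intervals positive;
`isi_cv = 0` gives deterministic trains).

For a control/test pair neither of which is rate-saturated in the relevant
window, the estimand has the closed form

$$\Delta F_{true} = r_c(\theta_t) - r_c(\theta_t - \Delta\theta_t) = g_c\,\Delta\theta_t,$$

implemented in `analytic_deltaf()`; saturation and window violations are
handled case by case and flagged.

Default pool parameters were fixed once, to land simulated discharge in the
physiological range reported for tibialis anterior in older adults: 40 units
per pool with exponential-spaced thresholds over (1, peak − 2) %MVT (dense
at low thresholds), minimum rate 7 pps, saturation 22 pps, mean gain
0.25 pps per %MVT (±15 % per-unit jitter), ISI CV 0.1, PNR ∼ N(35, 3.5²) dB,
and yield thinning that decomposes a unit with probability declining in
threshold (≈ 10–30 units per trial, as real decompositions return). Group
hysteresis profiles encode the cohort contrast of interest: the *sarcopenic*
profile has a lower hysteresis base (4.5 %MVT) that stays **flat** across
i20/i40/i60; *controls* (base 6.5) scale ×1/×1.25/×1.5 with intensity;
*athletes* (base 7.5) scale ×1/×1.4/×1.8. Default group sizes are 12/23/21.
Participant-level strength and function covariates are drawn from
group-typical distributions so that association models have realistic
structure.

What the simulator does **not** emulate: decomposition errors and duplicate
units, EMG waveforms, explicit channel dynamics, common synaptic noise
(units are conditionally independent given the drive), and — important for
brace height — the *accelerating* discharge phase that PIC amplification
produces in real units. The simulated rate-versus-drive relation is linear
up to saturation, so simulated trajectories have brace heights near zero.
Passing tests therefore demonstrate estimator correctness on a known model,
not fidelity of any particular biological value; brace-height validation
relies on constructed trajectories with closed-form geometry rather than on
pool simulations.

## Pipeline stages and the choices in them

**Validation and filtering.** Input is three tidy tables (per spike, per
torque sample, per participant). Schema violations and dangling references
are errors; a unit with non-monotone spike times or spikes outside its trial
is removed and reported. The pulse-to-noise-ratio gate keeps units with
PNR ≥ 30 dB (inclusive, per the conventional quality criterion). Torque is
low-pass filtered at 15 Hz with a 2nd-order zero-phase (forward–backward)
Butterworth filter; traces are point-reflected at both ends before filtering
so the zero-phase pass carries no startup transient. The order/phase
convention is the package's choice — the usual zero-lag convention for ramp
feedback signals.

**Discharge smoothing.** Instantaneous rates are reciprocal inter-spike
intervals; `instantaneous_rates()` reports them at the closing spike of each
interval (the rate is defined when the interval closes). For curve fitting,
`prepare_units()` re-centres each rate point on its interval midpoint: a
rate computed over $(t_{k-1}, t_k]$ estimates the rate at the middle of that
interval, and right-aligned placement would lag the whole curve by half an
ISI — enough to bias ΔF down by ≈ 0.1 pps on a 2 %MVT·s⁻¹ ramp. The smoothed
curve is an RBF-kernel ε-SVR evaluated on a 100 Hz grid over the active
interval, never extrapolated beyond the first/last spike. Hyperparameters
(config-overridable, recorded in the run manifest): C = 50, ε = 0.05 pps,
kernel width σ = half the median pairwise rate-point distance. The width
and tube size were calibrated once against the simulator's oracle: the
kernel must be narrow enough to track the rise and fall of a triangular
ramp (wide kernels leave the fit slack inside the ε-tube, adding ±0.1 pps
or more per evaluation point) yet wide enough to average over ISI jitter;
σ = median/2 with ε = 0.05 keeps noise-free per-pair ΔF error below 0.2 pps
while keeping the RMSE against the model rate under 0.5 pps at ISI CV 0.1.
A constant rate input returns a constant curve by construction.

**Events and bins.** Recruitment (derecruitment) is the first (last) spike;
thresholds are the filtered torque at those instants in %MVT; peak discharge
rate is the maximum of the smoothed curve. Bins partition (0, 60] %MVT as
(0, 20], (20, 40], (40, 60]; units recruited above 60 %MVT are flagged out
of the binned analyses.

**Pairing and ΔF.** Within each contraction every ordered (control, test)
pair is screened: control recruited before the test by at least 1.0 s and
with a lower threshold; control derecruited after the test; control
smoothed-rate modulation of at least 0.5 pps across the test's active
window; rate–rate correlation of at least 0.7 between the two smoothed
curves on a shared 100 Hz grid over their overlap. These thresholds are the
conventional values in the paired-motor-unit literature, not a transcription
of any single study's settings, and are config parameters logged in output.
ΔF is rate-at-recruitment minus rate-at-derecruitment (positive under
hysteresis; negative values are retained). Per test unit, ΔF values are
averaged over all eligible controls within a contraction, then across repeat
trials of the same intensity.

**Brace height.** The ascending trajectory re-parameterizes the smoothed
rate against torque from recruitment to the peak-discharge point (truncated
at the torque apex if the rate peaks later; non-monotone torque is replaced
by its running-maximum envelope and flagged). Because torque (%MVT) and rate
(pps) have incommensurable units, both axes are rescaled to [0, 1] over the
endpoint spans before any distance is computed; the reference line is then
$y = x$ and the right-triangle hypotenuse has length $\sqrt 2$. Brace height
is the perpendicular deviation at the point of maximal absolute deviation,
as a percentage of the hypotenuse, signed positive above the line.
Exclusion is deterministic (no manual review step): degenerate endpoints,
values above 100 %rTri, a *below-line* maximal deviation, or a negative
slope of the recruitment-point→brace-point segment in the normalized frame.
The slope rule's frame and segment are an interpretation fixed by this
package: the published rule names the quantity but not its frame. A
below-line maximum with positive rate (mildly convex trajectory) is excluded
as erroneous rather than reported negative, which keeps retained values in
[0, 100].

**Robust group models.** Per bin, `fit_bin_model()` fits
`outcome ~ group × intensity + sex + (1 | participant)` with motor units
nested in participants. Robustness is Huber M-estimation implemented as
iteratively reweighted `lme4::lmer()` fits: residuals are scaled by their
MAD, weights $\min(1, k/|r|/s)$ with tuning constant $k = 1.345$, iterated
to a coefficient tolerance of 1e-8 (cap 100 iterations). Estimated marginal
means are computed at balanced factor weights with sex averaged 50/50, with
Wald intervals from the fixed-effect covariance. When a factor has a single
level in the supplied data (e.g. one intensity), the corresponding terms are
dropped rather than erroring; an all-constant outcome returns exact zero
effects.

**Bootstrap contrasts.** Group and intensity contrasts get 95 % intervals
from a nonparametric cluster bootstrap: participants (the clusters) are
resampled with replacement — respecting the nesting of units in
participants — 2000 times by default; a resample that loses an entire group
is redrawn and counted. Intervals are bias-corrected and accelerated: the
bias correction $z_0$ comes from the bootstrap distribution's position
relative to the point estimate, the acceleration from a delete-one-cluster
jackknife. The resampling unit is a package decision (the alternative —
resampling motor units — ignores within-participant correlation). Resample
fits warm-start from the full-data Huber weights and run a shortened IRLS
(tolerance 1e-5, at most 10 steps); the contrast estimates are numerically
indistinguishable from fully iterated fits.

**Association models.** `fit_association_model()` fits
`ΔF ~ measure × sex × intensity (+ body mass) + (1 | participant)` by the
same robust machinery and reports per-stratum slopes (one per
sex × intensity cell) and predictive R² as the squared correlation between
observed and predicted outcomes — marginal (fixed effects only) and
conditional (fixed + random). By this definition R²c ≥ R²m in practice; both
are reported per fit rather than assumed.

**SDOC classifier.** `sdoc_classify()` applies the consortium cut-offs:
handgrip < 20 kg (female) / < 35.5 kg (male) **and** usual gait speed
< 0.8 m·s⁻¹; both criteria are required, missing inputs yield an
indeterminate flag.

## Numerical and degenerate-input conventions

* Smoothed curves are linearly interpolated between grid points; evaluation
  outside the active interval returns `NA` (pairs whose control curve is
  undefined at a test event are dropped with a diagnostic).
* Units with fewer than 4 rate points are flagged unsmoothable and counted,
  not errored.
* The percent difference between estimated marginal means uses the
  subtrahend (comparison-group) mean as denominator; the minuend-denominator
  alternative is also returned, since both conventions circulate.
* All randomness flows from one master seed; per-participant and per-trial
  seeds are derived deterministically, so identical configs produce
  byte-identical output files.

## Validation design and problem sizes

The test suite and the acceptance script validate each stage against an
independent oracle: ramp geometry for recruitment timing; the closed-form
ΔF for the pairing chain (noise-free pools of two participants at i20,
~300 eligible pairs, per-pair tolerance 0.2 pps; ISI CV 0.1 pools for mean
bias below 0.5 pps); a strict monotonicity sweep of injected hysteresis
Δθ ∈ {0,…,6} %MVT; exact point-to-segment distances for brace height (100
random trajectories, agreement to 0.1 %rTri); and parameter recovery on a
simulated cohort of 8 participants per group across all three intensities,
where the flat-sarcopenic/scaling-control/scaling-athlete design must yield
sarcopenic−control contrasts excluding zero at every intensity and a
control i20→i60 ΔF increase, using B = 500 bootstrap resamples. Null
calibration uses 100 replicate cohorts generated directly at the unit-ΔF
level (6 participants per group, 10 units per cell, participant intercept
SD 0.5, residual SD 0.8) with no group effect, requiring that at most 10 %
of 95 % Wald contrast intervals exclude zero; the Wald (rather than
bootstrap) interval is used there because the property concerns the contrast
estimator's calibration and a bootstrap within each of 100 replicates would
dominate runtime without changing the question. These problem sizes are the
package's validation choices; all scale up through the config.

## Known limitations

* The robust-LMM is an IRLS approximation to a joint robust fit: variance
  components are re-estimated by REML at each reweighting rather than by a
  robust criterion. This matches the "M-estimation" description but is not
  identical to, e.g., design-weighted robust REML.
* R²m/R²c are squared correlations (predictive), not variance-partition
  coefficients; they coincide with the usual mixed-model R² only
  approximately.
* Brace height on simulator output is near zero by construction (linear
  rate model); real discharge nonlinearity is validated geometrically, not
  biophysically.
* The eligibility thresholds (1.0 s, 0.5 pps, r = 0.7) are field-standard
  defaults, not fitted quantities; sensitivity to them should be explored
  per dataset via the config.
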