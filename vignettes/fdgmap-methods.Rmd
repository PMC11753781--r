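---
title: "Methods: FDG kinetic mapping, responder classification and behavioral metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FDG kinetic mapping, responder classification and behavioral metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable parameters, what the synthetic data do and
do not emulate, and the numerical and design choices made where the
underlying procedures left them open.

## The kinetic model

Dynamic [18F]FDG PET is modelled with the standard two-tissue-compartment
system. With plasma concentration $C_P(t)$, free tissue tracer $C_E$ and
phosphorylated tracer $C_M$:

$$\frac{dC_E}{dt} = K_1 C_P - (k_2 + k_3) C_E + k_4 C_M, \qquad
  \frac{dC_M}{dt} = k_3 C_E - k_4 C_M,$$

and the measured tissue signal is $C_T = C_E + C_M$. $K_1$
(ml·ml⁻¹·min⁻¹) is blood→tissue transport, $k_2$ efflux, $k_3$
phosphorylation and $k_4$ dephosphorylation (all min⁻¹). $C_T$ is the
convolution of $C_P$ with the impulse response

$$h(t) = \frac{K_1}{\alpha_2-\alpha_1}\left[(k_3+k_4-\alpha_1)
  e^{-\alpha_1 t} + (\alpha_2-k_3-k_4) e^{-\alpha_2 t}\right],\qquad
  \alpha_{1,2} = \tfrac12\!\left(s \mp \sqrt{s^2 - 4k_2k_4}\right),$$

with $s = k_2+k_3+k_4$. When the discriminant vanishes (for example
$k_2=k_3=k_4=0$, pure uptake) the code switches to the analytic confluent
limit $h(t) = K_1 e^{-\alpha t}[1 + (k_3+k_4-\alpha)t]$ rather than
dividing by a vanishing eigenrate gap. $h(0)=K_1$ always, and with
$k_4=0$, $h(\infty) = K_1 k_3/(k_2+k_3)$, the irreversible trapping rate.

No fractional-blood-volume term enters the tissue model; the blood signal
contributes only through the input function.

### Numerical evaluation

The input function follows a fixed interpolation contract: piecewise
linear between samples, zero before the first sample, flat after the last.
Under that contract the convolution with each exponential term has an
exact one-step recursion on a uniform grid, which the package evaluates in
compiled code on a 1-second grid and then averages over each frame
interval with the trapezoid rule (frames in the supported schedules start
and end on whole seconds, so the averaging is exact for the piecewise-linear
model output). The recursion coefficients switch to series expansions when
$\alpha\,\Delta t < 10^{-4}$ to avoid cancellation. An independent route to
the same prediction — stiff ODE integration of the state equations with
`deSolve::lsoda` at tolerance $10^{-10}$ — agrees with the analytic
convolution to better than $10^{-4}$ relative error across random
parameter draws ($K_1\in[0.01,0.5]$, $k_i\in[0,1]$); the test suite and
`scripts/acceptance.R` recompute this.

A curve sampled at frame mid-times (the natural timestamp of an extracted
TAC) extends flat over the tail of the last frame by the interpolation
contract; the coverage check therefore requires samples up to the start of
the final frame, not its end, so image-derived input functions are usable
without special-casing.

### Fitting

`fit_tac()` minimizes $\sum_i w_i\,(y_i - \hat y_i(\theta))^2$ with
Levenberg–Marquardt (`minpack.lm::nls.lm`) under box constraints.
Defaults, all configurable:

* start values $(K_1,k_2,k_3,k_4) = (0.1, 0.1, 0.05, 0.01)$ min⁻¹;
* bounds $[0, 2]$ min⁻¹ per parameter;
* weights proportional to frame duration (longer frames integrate more
  counts and carry lower variance; the true frame variances are unknown
  without reconstruction details, so duration is the pragmatic choice);
* up to five deterministic multiplicative restarts of the start vector if
  the first fit fails to converge — the restart table is fixed, so fits
  are pure functions of their inputs.

$k_4$ is fitted by default because four constants are part of the model,
but `pin_k4 = TRUE` fixes it at zero: over a 45-minute acquisition
dephosphorylation is weakly identified, and pinning trades a small bias
for variance. Which choice a given study used for its maps is usually not
stated; the package exposes both.

All-zero or non-finite voxel curves return a flagged non-converged result
with zero parameters instead of raising, so image fits never abort on
empty voxels. The derived transport ratio is
$C_E/C_P = K_1/(k_2 + k_3/\mathrm{LC})$ with lumped factor
$\mathrm{LC}=0.26$; it is strictly increasing in $K_1$ and decreasing in
$k_2$ and $k_3$, and is reported as `NA` where the denominator vanishes.

Noiseless forward-then-fit round trips recover all four constants to well
below 1% relative error; at 5% multiplicative frame noise the median
$K_1$ error is about 5%. The acceptance suite writes a bias/RMSE table at
CV ∈ {2%, 5%, 10%}.

## Input function and partial-volume correction

The image-derived input function is the per-frame unweighted mean over a
blood VOI, timestamped at frame mid-times. The VOI is supplied explicitly
(from configuration or phantom truth); automated vessel detection is out
of scope, mirroring manual aorta identification on an early frame. The
partial-volume correction divides the whole curve by a standardized
volume fraction of 0.6 — a pure spill-out model with no spill-in term,
which is exactly invertible and is inverted by construction on the
synthetic phantoms (blood voxels carry 0.6 × the frame-averaged input).
Whether an aortic TAC should be frame means or a fitted smooth curve is
left open by the usual description; frame means are used.

Note one deliberate asymmetry: the recovery guarantee of the noiseless
round trip is stated against the *generating* input function. The
image-derived route is coarser by construction (frame-averaged,
mid-time-sampled) and introduces a small shared bias; because the bias is
common to both groups it cancels from group contrasts, which is what the
end-to-end power simulation demonstrates.

## Voxel statistics

`voxelwise_ttest()` computes the unpaired two-tailed pooled-variance
Student's t per voxel, p from the t distribution with $n_A+n_B-2$ df, sign
convention A − B. No multiple-testing correction is applied by default —
raw p-value maps are the reported object; degenerate voxels (zero pooled
variance) are flagged rather than silently dropped. Cluster VOIs are
26-connected components of $\{p < \alpha\}$ with a minimum size, sorted by
size with ties broken by smallest linear index; the exact rule by which
significant regions become VOIs is rarely stated, so this one is
documented and deterministic. `voi_test()` then tests per-animal VOI
means, the standard guard against voxel-level selection effects.
Presentation re-gridding interpolates the p volume itself trilinearly to
0.1 mm, preserves node values exactly, never crosses the mask boundary
(any sample whose nonzero-weight nodes include an undefined voxel is
undefined), and is bounded by its enclosing nodes.

Under the null, the fraction of p < 0.05 voxels stays within three
binomial standard deviations of 5% across seeds; with a 15% K1 elevation
in one region (n = 8 vs 8, 5% frame noise) the full chain — simulate,
extract and correct the input function, fit, VOI test — detects the
effect in ≥ 90% of seeded repeats.

## Responder analysis

Calcium traces are corrected for photobleaching by fitting
$c + a\,e^{-bt}$ to the agonist-free baseline and subtracting the extended
fit. The fit uses Levenberg–Marquardt from several candidate rates because
the rate is poorly conditioned on short windows; if no start converges the
fallback is a straight line. The functional family is a documented choice —
the usual description says only that the baseline "was fit".

The response is the mean over the 4-minute window at the end of an
application minus the mean over the 4-minute window immediately before it,
and $\sigma$ is the sample SD of the baseline window. A cell is a
responder iff response $> 3\sigma$, *strictly*: a response of exactly
$3\sigma$ is not called. Negative (inhibitory) deflections are not called
responders by default; a signed mode exists. Responses are normalized to
the high-K⁺ (40 mM) deflection — the fluorescence at maximal
voltage-activated calcium influx — and cells without a positive high-K⁺
response are excluded as lacking a functional indicator. Population means
are tested with a two-tailed one-sample t-test; firing-rate changes with a
one-sample Wilcoxon signed-rank test. Firing series are reduced to 10-s
bins, with the baseline mean and SD over 24 bins (= 4 min).

Because the criterion compares a 48-sample window mean against the
single-sample baseline SD, its false-positive rate on white-noise traces
is far below 5%, and 6σ-amplitude responders are detected essentially
always; both rates are measured by the test suite. The main practical
hazard is bleach-trend extrapolation error, which is why the pipeline fits
the trend on the whole agonist-free head of the recording rather than on
the 4-minute quantification window alone.

## Behavioral metrics

CPP percentage excludes middle-area time from the denominator,
$100\,t_{paired}/(t_{paired}+t_{other})$, and is therefore invariant to
how long the animal sat in the middle. The CPP score is the percent change
of that percentage from pre-test to test day; with several pre-test days
the pre-test percentage is their mean (the aggregation rule is not usually
stated; the mean is the obvious symmetric choice). Two-bottle preference
is solution intake as a percentage of total drinking, tested against 50%.
Locomotor AUC integrates counts over a user-supplied window with the
trapezoid rule (the integration rule is not stated either; trapezoid is
additive over adjacent windows, which the tests exercise). The pre/post
window bounds are user-supplied because published figures mark them only
graphically.

## Synthetic data: what it emulates, what it does not

The generators are pure functions of (spec, seed); RNG state is saved and
restored, and per-animal seeds are `seed + animal index` (group B indices
follow group A's).

* **Input function** — a sum-of-exponentials bolus (shared fast rising
  edge, one fast and one slow decay term), delayed by 15 s, peaking near
  16 kBq/ml inside the first minute and decaying to a slow metabolic tail.
  Real aortic curves are measured, not parametric; the family is smooth,
  integrable and non-negative by construction.
* **Phantom** — 20 × 20 × 10 voxels at 0.4 × 0.4 × 0.8 mm by default (a
  desk-scale stand-in for a mouse brain volume; fitting it takes minutes,
  not hours), three tissue regions with distinct plausible kinetics, a
  blood pool at 0.6 × the frame-averaged input, multiplicative Gaussian
  frame noise with fixed CV (default 5%). Real PET noise is
  reconstruction-shaped and spatially correlated; since reconstruction is
  out of scope, the noise level is a free parameter of the simulation, not
  a claim about any scanner, and passing tests bound estimator behavior
  under this noise model only.
* **Group studies** — group B applies per-region K1 multipliers; between-
  animal variability beyond frame noise (anatomy, physiology, motion) is
  not simulated, so simulated power is an upper bound on real power at the
  same effect size.
* **Traces** — baseline × exp(−bleach·t), an 8-minute agonist window whose
  last 4 minutes are the response window, a terminal high-K⁺ deflection,
  additive white noise. Real GCaMP data add movement, drift
  nonstationarity and correlated noise.
* **Behavior tables** — CPP session times that conserve the 1800-s
  session, daily two-bottle intakes, and a counts-per-minute activity
  series with a transient post-injection elevation at t = 60 min.

## Problem sizes and runtimes

The shipped tests use the 25-frame schedule throughout, the full
20 × 20 × 10 phantom for the noiseless recovery check, 100 seeded repeats
of the n = 8 vs 8 power study on the compact 10 × 10 × 5 phantom
(`compact_phantom_spec()`, 18-voxel target region), 1000 null traces for
the false-positive rate, and 200 random parameter draws for the
forward-model equivalence. These sizes were chosen so the whole suite runs
in minutes on one core while every rate estimate keeps a usable binomial
confidence width.

## Known limitations

* No Patlak/Logan graphical methods, basis-function or spectral fitting;
  no metabolite or dispersion correction of the input function.
* The spill-out-only partial-volume model ignores spill-in from
  surrounding tissue.
* Cluster inference is descriptive (size threshold on raw p-maps), not
  permutation-calibrated.
* k4 estimates at 45 minutes are weakly identified; treat fitted k4 maps
  with caution or pin k4.
* The 3σ criterion is one-sided toward activation by default.
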