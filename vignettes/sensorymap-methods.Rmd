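---
title: "Methods: psychophysics and percept mapping for SCS sensory studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psychophysics and percept mapping for SCS sensory studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensorymap)
```

`sensorymap` analyzes the sensations evoked by epidural spinal cord
stimulation (SCS) in people with upper-limb amputation: where the sensations
are felt, how detectable and discriminable they are, how their perceived
intensity scales with stimulus amplitude, and how stable they remain over
weeks of a percutaneous implant. This vignette documents the models, the
tunable parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the design decisions
taken where the methodology was genuinely open.

## The psychometric model

All two-alternative forced-choice (2AFC) behaviour is modeled with the
cumulative-normal psychometric function

$$\Psi(x) = \gamma + (1 - \gamma - \lambda)\,\Phi\!\left(\frac{x - \mu}{\sigma}\right),$$

where $x$ is the stimulus amplitude in mA, $\gamma$ the guess rate, and
$\lambda$ the lapse rate. For a two-interval task $\gamma = 0.5$; $\lambda$
is fixed at 0 for fitting, matching the constraint under which the
thresholds are defined, and is configurable in the simulated observer for
robustness exercises. `fit_psychometric()` maximizes the binomial
log-likelihood over $(\alpha, \log\beta)$, with location $\alpha = \mu$ and
slope $\beta = 1/\sigma$ (per mA; multiply amplitudes by 1000 to read the
slope per µA when comparing against µA-scale reports).

Numerical choices:

* **Multi-start optimization.** The likelihood is seeded on a coarse grid
  (15 locations spanning 1.5× the stimulus range × 7 log-spaced slopes); the
  best 8 grid points are refined by BFGS with a relative tolerance of
  1e-12 on the negative log-likelihood. Near-degenerate data produce long
  plateaus; the grid keeps the quasi-Newton refinement out of the wrong
  basin, and tests verify grid-oracle dominance on small instances.
* **Probability clamping.** $\Psi$ is clamped to $[10^{-12}, 1-10^{-12}]$
  so degenerate parameters yield finite (very poor) likelihoods rather than
  `-Inf`.
* **Degenerate data.** Levels that are all-correct, all-incorrect, or all at
  identical accuracy cannot identify both parameters; the fit is returned
  with `converged = FALSE` rather than an arbitrary answer.
* **Repeated amplitudes** are merged into single binomial levels before
  fitting.

The detection threshold is the amplitude at 75% accuracy,
`threshold_at(fit, 0.75)`; with $\gamma = 0.5$, $\lambda = 0$ this is
*identically* $\alpha$, a fact the tests assert symbolically. Tasks whose
per-level accuracies sit entirely below 0.6 or entirely above 0.9 carry no
threshold information and are excluded (`exclusion_check()`). Exclusion is
applied per task, and day-repeated thresholds for an electrode are averaged
afterwards (`aggregate_thresholds()`); the alternative order (average, then
exclude) was rejected because a single uninformative session should not
drag an informative one out of range.

### Goodness of fit (pTLR)

`gof_ptlr()` implements the parametric bootstrap: simulate `n_sim` (default
1000) datasets from the fitted $\Psi$ at the observed levels and trial
counts, refit each, and compute each deviance
$D = 2(\ell_{\text{sat}} - \ell_{\text{model}})$ against the saturated
model. The reported pTLR is the fraction of simulated deviances at least as
large as the observed one — equivalently the fraction of simulated
likelihood ratios smaller than the data's — so it spans 0–1 with higher
values signifying a better fit; fits with pTLR < 0.05 are discarded from
threshold summaries. Bootstrap refits are warm-started at the generating
parameters (with two log-slope offsets as fallbacks); refit failures are
counted and the result is flagged if more than 10% fail. Under the true
model the pTLR distribution is approximately uniform; the test suite checks
the rejection rate at 0.05 and the Kolmogorov–Smirnov distance to
uniformity.

### Just-noticeable differences

JND trials present a standard (2.5 or 4.0 mA) and a test amplitude, scored
as correct when the truly-higher interval is chosen. The package pools over
whether the test fell above or below the standard by fitting $\Psi$ over the
absolute difference $|x_\text{test} - x_\text{standard}|$; the JND is the
$|\Delta|$ at 75% accuracy. Signed-$\Delta$ fitting was the alternative;
$|\Delta|$ was chosen because the comparison lists in such experiments are
typically symmetric and the discrimination judgment is on magnitude, and
the choice is surfaced here rather than buried.

## The adaptive staircase

`run_staircase()` is a one-up three-down transformed up-down tracker:
an incorrect response raises the amplitude, three consecutive correct
responses lower it, and every change is a fixed 2 dB step. Decibels are
amplitude (field-quantity) decibels — one step multiplies the amplitude by
$10^{2/20} \approx 1.259$ — because amplitude, not power, is the controlled
variable. Conventions the trial record enforces:

* The consecutive-correct counter resets after any amplitude change and
  after any incorrect response.
* A reversal is an actual flip in the sign of the applied step; a step
  clipped into no-change at the bounds (0 and 6 mA, the stimulator ceiling)
  does not create a reversal.
* The run terminates at the fifth reversal (configurable), with a trial cap
  (default 200) guarding non-termination; a capped run is flagged and has
  no threshold.
* The threshold estimate is the mean amplitude of the 10 trials up to and
  including the trial whose response triggered the terminating reversal.
  The "trials before the fifth direction change" phrasing is ambiguous
  about that boundary trial; it is included here because the direction
  change is an event that follows the trial's response. With fewer than 10
  such trials, all available are averaged and a warning is raised.

One-up three-down theory targets the 79.4% point of $\Psi$
($\Phi^{-1}$ of $\sqrt{0.5}$ above the mean), while the estimator is often
described as a 75% threshold. The package does not adjudicate: it reports
both the estimate and $\Psi(\text{estimate})$, and the convergence test
accepts the 72–80% band that brackets both conventions. Simulated at the
default design (observer $\mu = 2$ mA, $\sigma = 0.4$ mA, start 1 mA), 500
runs land near 79%.

## Magnitude estimation and binned discriminability

Free magnitude estimation gives an open-ended rating per stimulus, with 0
meaning "not perceived". Preprocessing (`preprocess_magnitude()`) drops the
first block — the subject is still establishing their subjective scale —
and divides the remaining ratings by their mean, zeros included, so every
electrode/session has mean response 1. Including zeros in the mean was a
judgment call (the convention is unstated in most protocols); excluding
them would inflate the normalized scale of electrodes with many
sub-threshold trials. Normalization is idempotent, which the tests check.

`fit_intensity_models()` compares a linear fit (with the two-sided F-test
p-value `p_int` for zero slope), a logarithmic fit $y = a + b\ln x$, and a
3-parameter logistic $y = L/(1+e^{-k(x-x_0)})$ on adjusted $R^2$, with the
linear model winning ties. The logistic is fit by Levenberg–Marquardt
nonlinear least squares; non-convergence records its adjusted $R^2$ as
missing and the comparison proceeds. The logistic was fixed as the sigmoid
form because it is the standard saturating psychophysical alternative and
has interpretable parameters.

`bin_discriminability()` asks how many intensity levels a subject could
reliably distinguish: per electrode, amplitudes are normalized to the
maximum amplitude tested and ratings to the maximum rating reported —
each maximum taken over all of that electrode's sessions, so that a
session-specific ceiling does not shift the bins — then both are cut into
$k$ equal-width bins on $[0,1]$, half-open with the last bin closed so the
maximum maps to the top bin. Accuracy is the per-trial fraction of matching
bin indices pooled across electrodes and subjects (per-electrode accuracies
are available as an option); zero ratings fall in bin 1. On noise-free
proportional data the accuracy is exactly 1 for any $k$; on permuted
ratings it falls to $\approx 1/k$ — both ends are asserted in the tests.

## Percept drawings and spatial stability

Drawn percepts are binary rasters on a calibrated arm template
(`arm_template()`, default 0.5 mm/px) segmented into eight regions ordered
distal-first: thumb, digits 2–3, digits 4–5, palm, wrist, forearm, elbow,
upper arm. Two independent calibration constants anchor pixels to physical
units, each applied only to its own quantity: distances use the average
hand length (189 mm between the fingertip and wrist landmarks), areas use
the average palmar area (75 cm² for the palm region's pixel count). The two
constants need not be mutually consistent on a schematic template, which is
exactly why each is confined to its own quantity. All pixel-to-physical
conversions live in the template object.

* `mask_area_cm2()` and `mask_centroid_mm()` are plain pixel counting and
  unweighted pixel-center means; tests compare them against brute-force
  pixel-list oracles exactly.
* `overlap_fraction()` divides the intersection by the *smaller* mask's
  area, so containment scores 1; the 70% display rule then keeps the more
  focal percept, which is the purpose that denominator serves.
* `select_reference_amplitude()` picks the amplitude covering the most
  distinct weeks (at least two), breaking ties toward the minimum
  amplitude; electrodes with no two-week amplitude are excluded.
* `weekly_stability()` reports per-week mean centroid and mean area, the
  Euclidean migration between consecutive weekly mean centroids, and the
  week-over-week area change both signed and absolute. Weekly medians of
  the absolute change are the headline stability numbers, but the signed
  series is what the AR(1) trend model consumes — a shrinking percept has a
  negative trend even though its absolute changes are positive. Missing
  weeks produce recorded gaps, never two-week differences in disguise.
* Only hand-region percepts belong in stability analyses; masks whose
  maximal-overlap region is not in the hand can be filtered with
  `assign_body_region()` before `weekly_stability()`.

## Modality classification and dermatome tables

Reports use a fixed descriptor vocabulary grouped as mechanical (touch,
pressure, sharp), tingle (electrical, tickle, itch, pins-and-needles),
movement (vibration, across-skin, body/limb/joint), and temperature. The
paresthetic set is defined by the classification rule, not the vocabulary
columns: electrical tingle, pins-and-needles, sharp, or tickle. A report
containing only paresthetic descriptors is paresthetic; paresthetic plus
any mechanical/movement/temperature content is mixed; no paresthetic
descriptor is naturalistic. The three classes partition every report.
Notably 'sharp' sits in the mechanical column yet is paresthetic, while
'itch' sits in the tingle column yet is not; the rule wins, and an
`include_itch` switch exposes the alternative reading. Temperature counts
as non-paresthetic content.

`sunburst_counts()` produces the tingle → mechanical → movement hierarchy
(child counts never exceeding parents), and `dermatome_proportions()` gives,
for each anatomical region, the distribution over spinal levels of the
electrodes that evoked it — ipsilateral percepts only, electrodes evoking
exclusively bilateral or contralateral sensations excluded, and
never-evoked regions reported as `NA` columns, distinguishable from
structural zeros.

## Threshold-charge stability, AR(1) trends, and lead geometry

Threshold charge is first-phase amplitude × first-phase pulse width
(mA·µs = nC); with charge-balanced pulses the first phase carries the
conventional amplitude. Week effects are tested with classical one-way
ANOVA and Tukey HSD pairwise comparisons (`anova_by_week()`, via
`stats::aov`/`TukeyHSD`, i.e. Tukey–Kramer under unbalanced weeks); weeks
with fewer than two values are dropped with a warning.

`ar1_regression()` fits $y_t = a + b\,t + u_t$, $u_t = \rho u_{t-1} +
\varepsilon_t$, by iterated feasible GLS: $\rho$ is re-estimated from lag-1
residual products and the Prais–Winsten quasi-differenced regression
(retaining the first observation with its stationary weight
$\sqrt{1-\rho^2}$) is refit until $\rho$ converges (tolerance 1e-8, cap 50
iterations). Trend inference comes from the transformed regression's
t-statistic; the Durbin–Watson statistic of the OLS residuals is reported
as the autocorrelation diagnostic, and $|\hat\rho|$ reaching the 0.999
bound flags non-stationarity. When the residuals carry no lag-1 structure
the procedure reduces exactly to OLS. The estimator is cross-checked in the
tests against an independent maximum-likelihood GLS fit (`nlme::gls` with
an AR(1) correlation structure); reproducing any particular proprietary
AUTOREG output coefficient-for-coefficient is explicitly not a goal.

Lead geometry is the arithmetic downstream of manually picked landmarks:
`affine_from_landmarks()` solves the least-squares 2D affine alignment
(exact on noise-free landmarks, rank-deficiency on collinear ones),
`contact_scale()` converts a 3 mm contact's pixel length into mm/px, and
`rostrocaudal_migration()` projects weekly tip displacements onto the
rostro-caudal axis (caudal positive) and medians them across leads.

## The synthetic-study generator

`generate_study()` emits a complete study in the same file formats the
pipeline consumes — CSV trial/rating/report/charge/track tables, PNG + JSON
percept masks, and a ground-truth JSON — from one master seed, with fixed
per-electrode substream offsets so studies are byte-identical under the
same (config, seed). It emulates:

* binomial 2AFC responses from cumulative-normal observers (guess rate 0.5,
  lapse 0 by default), with per-electrode thresholds drawn from 1–2.5 mA
  and spread at 20% of threshold — the range where real detection
  thresholds concentrate under a 6 mA ceiling;
* discrimination observers at the 2.5/4.0 mA standards with true JNDs of
  0.08 and 0.3 mA, reproducing the Weber-like growth of JND with standard
  amplitude at realistic magnitudes;
* linear amplitude→rating growth (gain 0.8–1.6 per mA) with additive
  Gaussian noise truncated at zero (a lognormal option exists), zero below
  the detection floor;
* weekly-drifting elliptical percepts (default 5 mm/week drift, −5% area
  per week, 2 mm within-week jitter) rasterized on the calibrated template;
* multinomial descriptor-combination reports from a configurable profile
  (default dominated by tingle-pressure mixtures, with smaller naturalistic
  and pure-paresthetic fractions);
* weekly threshold charges with a mild week effect, and lead tips whose
  caudal migration is largest in week 1 and decays after — the
  settling pattern seen in percutaneous leads.

It deliberately does **not** emulate neural recruitment or electric fields,
referred residual-limb co-sensations (beyond labelled extra masks), subject
fatigue or criterion drift, non-stationary psychometric parameters, or
drawing artifacts (holes, multi-stroke outlines). Passing tests on
synthetic data therefore demonstrate that the estimators recover known
parameters under the stated noise models — not that real percept drawings
are ellipses or that real rating noise is Gaussian.

## Problem sizes used in the tests

Parameter-recovery and calibration tests run at sizes chosen to make the
statistical assertions sharp while keeping the default suite quick: 500
staircases for the convergence band; 100 replicates of 6 levels × 60 trials
for location recovery (median error < 0.1 mA, bias < 5% of sigma); 200
outer × 250 inner simulations for pTLR calibration (rejection rate 5% ± 2%,
KS distance < 0.1); 2000 simulations for ANOVA type-I calibration; 50–60
series of length 200 for AR(1) recovery (median trend error < 0.03). The
full pipeline test uses a 2-subject × 3-electrode, 4-week study.

## Known limitations

* The psychometric fitter holds $\gamma$ and $\lambda$ fixed; free-lapse or
  Bayesian estimation is out of scope, as are non-normal link functions.
* Staircase support is limited to the one-up n-down family; QUEST/PEST-type
  adaptive rules and interleaved tracks are not implemented.
* The AR(1) model is first-order with a single series; panel pooling across
  electrodes is the caller's choice (the pipeline averages per week before
  fitting, and documents that choice rather than hiding it).
* Templates are 2D schematics; registration across subjects' templates and
  3D limb models are not attempted.
* The overlap display rule and focality conventions assume same-template
  masks; cross-laterality comparisons are excluded by design.
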