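---
title: "Methods: alpha power, alpha slowing, and their statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha power, alpha slowing, and their statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphaspec)
```

`alphaspec` implements a complete source-space alpha-band analysis for
three-group cognitive-decline cohorts: synthetic cohort generation, an
optional beamformer stage, multitaper relative-power spectra, IAF-anchored
band power, Gaussian-peak/power-law spectral parameterization, cluster-based
permutation inference with an age covariate, and an FDR-corrected
regression battery. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic cohort does and does
not establish about real recordings.

## The synthetic cohort

The generator is first-class, tested code: it defines the statistical world
in which every downstream stage is validated.

Each group g has a latent alpha peak frequency law N(mu_g, sigma_g)
truncated to (4, 14) Hz (defaults 9.8/9.6/9.0 Hz, SD 0.9, groups of
39/41/51 — the structure of an elderly no-SCD/SCD/MCI cohort), a latent
alpha relative power law (defaults 0.32/0.27/0.25, SD 0.06), and an age law
(70.4/71.6/73.0 years). The relative-power means have no published
reference values; 0.2–0.4 is the realistic range for posterior alpha
relative power over a 2–45 Hz normalization span in resting eyes-closed
recordings, and the group ordering mirrors the reduced alpha power expected
along the SCD/MCI continuum. These were fixed once, before any calibration
against results.

Signals are the simplest process satisfying the pipeline's assumptions: per
epoch and source, a sinusoid at the subject's latent peak frequency with
uniform random phase, added to 1/f^e Gaussian background noise (e = 1)
synthesized by spectral shaping of white noise. The sinusoid amplitude is
calibrated analytically: with one-sided background bin powers w_k
proportional to f_k^-e, the amplitude a solves

p = (a^2/2 + N_alpha) / (a^2/2 + N_band),

where p is the target alpha relative power and N_alpha, N_band are the
background powers inside the subject's alpha band and inside 2–45 Hz. The
target is achievable only when p exceeds the background's own alpha
fraction N_alpha/N_band (about 0.16 at e = 1); the latent draw is therefore
truncated to that feasible region plus a 0.02 margin. The calibration is
approximate — taper leakage and finite epochs move the measured value by a
few hundredths — and is verified post hoc by the spectral tests, which
check that measured band power tracks the target and increases strictly
with the generator's alpha amplitude.

Scores (14 neuropsychological criteria and ICV-normalized hippocampal
volume) are affine in the latent truths:
`score = intercept + beta_power * relpower + beta_peak * iaf + noise`. The
default slopes are non-zero for exactly the criteria where the
corresponding predictor should carry signal in the emulated design (11
criteria driven by peak frequency, 5 by alpha power), with magnitudes taken
from the reported scale of such associations and intercepts anchored so the
control group hits its reference means. Because groups differ in latent
IAF, group differences in scores emerge mechanistically from the slowing.

Reproducibility: one cohort-level seed governs the subject table; each
subject's epochs are drawn under a seed derived deterministically from the
cohort seed and subject index, so epochs can be regenerated on demand
(`subject_epochs()`) instead of being stored — cohorts at realistic source
counts stay memory-light, and two runs with the same configuration are
bitwise identical.

**What the generator does not emulate:** head geometry and anatomically
placed generators (the grid is an abstract cubic lattice), amplitude
dynamics and non-sinusoidal waveform shape, artifacts, sensor physics, sex
and education effects (descriptive columns only, no signal path). Passing
tests therefore demonstrate correctness of the estimators and inference
machinery under a known generative model — not robustness to the full
physiology of MEG recordings.

## Forward and inverse stage

The leadfield is synthetic: Gaussian sensor gains per source, smoothed
across neighbouring grid sources with a squared-exponential kernel (length
15 mm) and column-normalized. It stands in for an anatomy-derived forward
model so the LCMV path can be exercised end to end; it is labelled
synthetic throughout.

The beamformer is the scalar (fixed-orientation) Van Veen LCMV filter
w_s = (l_s' C^-1 l_s)^-1 l_s' C^-1 built from the epoch-averaged sensor
covariance, regularized by `reg * trace(C)/n` on the diagonal
(default reg = 0.05, exposed in the configuration; orientation handling and
regularization are design choices of this package, not reconstructions of
any particular study's settings). Unit gain at the target source is an
invariant checked to 1e-6 for every generated filter; a noiseless single
dipole must be reconstructed with correlation at least 0.999.

Band-pass filtering is zero-phase Butterworth (forward–backward), a
high-pass of order 3 at 2 Hz cascaded with a low-pass of order 5 at 45 Hz.
The cascade was chosen over a single band-pass design for numerical
stability at low normalized corner frequencies; orders are the smallest
meeting the stop-band contract of at least 20 dB attenuation one octave
outside the band after the double pass. Real recordings are padded with
adjacent signal before filtering; synthetic epochs have no context, so
epochs are mirror-padded (`pad_seconds`, default 2 s) and trimmed, keeping
edge transients outside the retained window.

## Spectral estimation

Multitaper PSD with DPSS tapers. The tapers come from the classical
symmetric tridiagonal eigenproblem (no installed package provides Slepian
sequences); they are verified in tests against independently computed
reference values and for orthonormality and concentration. The
time-bandwidth product is set by the epoch length and the smoothing
half-bandwidth: NW = T x W, K = 2NW - 1 tapers. The defaults — 4-s epochs,
0.5 Hz smoothing — give NW = 2 and 3 tapers. Requesting smoothing too small
for the epoch length (NW < 1) is an error, not a silent fallback.

The frequency axis is 2–45 Hz in 0.5 Hz steps. 4-s epochs have 0.25 Hz
native resolution; the axis is taken by decimating native bins rather than
zero-padding (a `zero_pad` switch interpolates the grid by padding when the
axis is not natively representable). Relative power divides each source row
by its own total over the axis, so rows sum to 1; the operation is
idempotent and scale-invariant, and zero-power rows are an error naming the
source.

IAF detection is automated (a human rater identified peaks in the original
workflow): the spectrum is averaged over a posterior region of interest
(lowest third of the grid along the y axis by default — an abstract stand-in
for occipito-temporal channels), and the IAF is the frequency of the
highest local maximum within the search range, default 6–13 Hz (the range
is this package's choice). If no local maximum exists — e.g. a pure 1/f
spectrum — the in-range argmax is returned with a `fallback` flag rather
than an error, so downstream code can exclude or inspect such subjects.
The alpha band is [IAF - 2.5, IAF + 2] Hz; band edges are inclusive and
bins are point frequencies, so a partition of 2–45 Hz has band powers
summing to exactly 1. Bands extending outside 2–45 Hz are rejected.

## Alpha peak parameterization

Each source row is fitted over 4–14 Hz to

P(f) = A f^-B + C exp(-(f - f_p)^2 / Delta^2).

This five-parameter Gaussian-peak/power-law form is the standard spectral
parameterization with these symbols; with Delta^2 (not 2 Delta^2) in the
denominator, Delta is the 1/e half-width. The convention is internal: the
recovery tests generate from the same form they fit, and f_p — the only
parameter carried forward — is unaffected by the width convention.

Numerics: bounded Levenberg–Marquardt least squares (`minpack.lm`), bounds
B in [0, 4], Delta in [0.2, 5] Hz, f_p in the fitting range, A, C >= 0.
Multi-start over the f_p initialization: the argmax of the row minus a
log-log linear baseline within 7–13 Hz, plus fixed alternates at 8 and
11 Hz; B starts at 1, Delta at 1 Hz. The best SSE wins; exact ties break
toward lower f_p. A peak is declared present when C is at least 5% of the
fitted background at f_p — there is no published rejection rule, and 5% is
low enough to keep genuine small peaks while discarding pure-background
rows; flagged and non-converged rows propagate as missing f_p. Noiseless
model-generated rows must be recovered to 1e-3 in all five parameters, and
the fit is scale-equivariant, so raw and relative-power rows behave
identically.

## Group inference

Scalar measures use ANCOVA: `value ~ group + age`, the nested-model F test
for the factor, and emmeans-based covariate-adjusted means with Tukey HSD
contrasts computed when the factor is significant at 0.05. Type-I error is
verified by simulation (1000 null datasets) to be 0.05 within Monte-Carlo
tolerance.

Per-source maps use cluster-based permutation tests. Design choices that
the underlying methodology leaves open, and how they are fixed here:

* **Statistic**: the covariate-adjusted group t from `value ~ group + age`
  per source (equivalently signed sqrt-F for two groups), keeping
  directional cluster maps; positive and negative clusters are formed
  separately and tested against the null of the maximum absolute cluster
  mass.
* **Cluster-forming threshold**: parametric p < `cluster_alpha` (default
  0.05) on the per-source t. Exposed in the configuration since no
  canonical value exists.
* **Covariate scheme**: Freedman–Lane — fit the reduced (age-only) model,
  permute its residuals, add back the reduced fit, recompute the statistic.
  This is the accepted default for permutation inference with nuisance
  covariates. With no covariate the scheme reduces to plain label
  permutation, and for small samples an exhaustive enumeration over label
  assignments is available; tests require Monte-Carlo and exhaustive
  p-values to agree within 2/sqrt(n_perm).
* **Missing values** (sources without a detectable peak): subjects are
  dropped per source; sources with below 80% subject coverage are excluded
  from testing. Permutations are derived from one global subject
  permutation so that sources sharing a missingness pattern stay coherent.
* **p-values**: (1 + #{null >= observed})/(n_perm + 1), so the smallest
  attainable p is 1/(n_perm + 1); default n_perm = 2000, with 500 used in
  the calibration suites.

Family-wise error under a simulated null is verified to stay at or below
0.07 over 200 datasets, and a planted 8-source connected effect must be
recovered with cluster–truth Jaccard overlap of at least 0.5.

## Regression battery

Per criterion, ordinary least squares
y = beta0 + beta1 x1 + beta2 x2 + e with x1 the source-averaged alpha
relative power and x2 the source-averaged peak frequency, both entered in a
single step; predictors are unstandardized by default (coefficients on the
raw scale) with a z-scoring switch for conditioning. Benjamini–Hochberg FDR
at q = 0.1 is applied over the pooled family of all slope p-values (2
predictors x 15 criteria = 30 tests): one stated correction, one family.
The alternative reading — correcting each predictor's 15 p-values
separately — is available as `family = "per-predictor"`. Hippocampal volume
enters exactly like a score. Under a full null the flagged proportion
respects q; with the default generator the planted significance pattern is
recovered with sensitivity at least 0.8 at the default cohort size.

## Problem sizes

Defaults are desk scale, chosen so a full pipeline run and the complete
test suite execute comfortably on a single CPU: 250 Hz sampling (the
methodology transfers unchanged to 1000 Hz), 20 four-second epochs per
subject (cohorts in this field average ~45, with a 15-epoch inclusion
floor), and a 5x5x5 source grid standing in for a ~2500-source 1-cm brain
grid. The test suites use 2x2x2 or 3x3x3 grids, 6–10 epochs, and 150–500
permutations; the acceptance script recovers group-mean peak frequencies
with 39- and 51-subject groups, 20 epochs, and 27 sources. All sizes are
configuration, not code.

## Known limitations

* The generator's stationary sinusoid-plus-1/f model cannot probe
  sensitivity to bursty alpha, moving peaks within a recording, or
  non-sinusoidal harmonics (which the peak fit could misattribute).
* The synthetic leadfield has no null space structure of real MEG physics;
  beamformer performance under correlated sources or rank-deficient
  covariances is exercised only minimally.
* Single-peak parameterization: split alpha peaks fit as one compromise
  Gaussian; knee-parameterized aperiodic components are out of scope.
* The IAF search default (6–13 Hz) and posterior-ROI definition are
  reasonable but arbitrary; both are configuration.
* Cluster inference assumes exchangeability of residuals across subjects
  under the null; heavy heteroscedasticity between groups would distort
  calibration.
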