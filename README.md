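# alphaspec

Source-space alpha-band spectral analysis for cognitive-decline cohorts.

Resting-state MEG/EEG studies of the Alzheimer's-disease continuum ask two
related questions about the dominant ~10 Hz alpha rhythm: is its **relative
power** reduced, and is its **peak frequency** slowed, in elders with
subjective cognitive decline (SCD) and mild cognitive impairment (MCI)
compared with healthy controls — and do these spectral parameters track
cognition and hippocampal atrophy? `alphaspec` implements that analysis as a
tested, reusable R pipeline, driven by a synthetic cohort generator so every
stage is verifiable without access to raw recordings.

The package is for methodologists and students of M/EEG spectral statistics:
all stages are plain R functions over tibbles, with `tidy()`/`glance()`
accessors and `autoplot()` methods.

## What it computes

* **Synthetic cohorts** — three groups (no-SCD / SCD / MCI, sizes 39/41/51 by
  default) with latent alpha peak frequencies drawn per group from
  N(9.8, 0.9) / N(9.6, 0.9) / N(9.0, 0.9) Hz truncated to (4, 14), ages,
  neuropsychological scores and ICV-normalized hippocampal volumes generated
  from the latent spectral parameters, and 4-s source-space epochs: a
  sinusoid at the latent peak over 1/f background noise, calibrated so a
  target alpha relative power is achieved.
* **Forward/inverse (optional)** — a synthetic leadfield over a regular
  cubic source grid, 2–45 Hz zero-phase band-pass with mirror padding, and
  an LCMV beamformer (Van Veen weights `(lᵀC⁻¹l)⁻¹lᵀC⁻¹` from the
  epoch-averaged covariance, unit gain at each source).
* **Spectra** — DPSS multitaper power spectral density, 2–45 Hz in 0.5 Hz
  steps with 0.5 Hz smoothing (NW = 2, 3 tapers for 4-s epochs), normalized
  to relative power over 2–45 Hz.
* **IAF and band power** — the individual alpha frequency (IAF) as the most
  prominent peak of the posterior-ROI average spectrum; the alpha band
  anchored at **[IAF − 2.5, IAF + 2] Hz** (a 9.4 Hz sample-average IAF gives
  6.9–11.4 Hz); band relative power summed per source. Theta ([4, 6.9] Hz)
  and beta ([12, 30] Hz) are available as secondary bands.
* **Alpha peak parameterization** — each source spectrum fitted over
  4–14 Hz to a Gaussian peak on a power-law background,

  P(f) = A·f<sup>−B</sup> + C·exp(−(f − f<sub>p</sub>)² / Δ²),

  by bounded multi-start nonlinear least squares; f<sub>p</sub> is the alpha
  peak frequency carried into group analyses.
* **Group inference** — age-adjusted ANCOVA with Tukey HSD for scalar
  measures; cluster-based permutation tests (CBPT) over the source grid for
  per-source alpha power and peak frequency: covariate-adjusted t maps,
  clusters formed at parametric p < 0.05 under grid adjacency, maximum
  cluster-mass null from 2000 Monte-Carlo permutations with the
  Freedman–Lane scheme for the age covariate.
* **Regression battery** — per criterion (14 cognitive scores plus
  hippocampal volume), y = β₀ + β₁·(alpha power) + β₂·(peak frequency) + ε
  with both predictors entered in a single step, Benjamini–Hochberg FDR at
  q = 0.1 over the pooled coefficient family.

## Worked example

```r
library(alphaspec)

cfg <- pipeline_config(
  cohort = cohort_config(n_per_axis = 3, epoch_count = 10, seed = 1),
  n_perm = 500)
report <- run_pipeline(cfg)
report
#> <pipeline_report> 131 subjects, 27 sources (seed 1)
#>   overall IAF: 9.3 Hz
#>   alpha_relpower: significant clusters per contrast: noSCD_vs_SCD=1, noSCD_vs_MCI=1, SCD_vs_MCI=0
#>   f_p: significant clusters per contrast: noSCD_vs_SCD=1, noSCD_vs_MCI=1, SCD_vs_MCI=0
#>   regression battery: 16/30 FDR-significant coefficients
```

The report aggregates every stage. The weighted overall IAF of the measured
cohort is 9.3 Hz here (the configured group means weighted by 39/41/51 give
9.4); the MCI contrasts show the planted slowing as spatial clusters:

```r
tidy(report$contrasts$f_p$noSCD_vs_MCI)
#> # A tibble: 1 × 6
#>   cluster n_sources sources     mass p_value significant
#>     <int>     <int> <list>     <dbl>   <dbl> <lgl>
#> 1       1        27 <int [27]> -109. 0.00200 TRUE
```

(negative mass: lower peak frequency in the MCI group across all 27
sources, cluster p = 1/501 at 500 permutations). Peak frequency also
predicts cognition — e.g. its FDR-flagged coefficient for immediate recall
is 4.57 ± 1.13 points per Hz:

```r
dplyr::filter(tidy(report$battery), term == "peak_freq", fdr_significant)
```

Each result object also has `glance()` and `autoplot()` methods, and
`write_cohort_csv()` / `pipeline_config(output_dir = ...)` persist all
tables as CSV. A thin command-line wrapper is installed at
`inst/scripts/alphaspec-pipeline.R`.

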