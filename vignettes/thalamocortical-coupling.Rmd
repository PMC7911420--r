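---
title: "Static and dynamic thalamocortical connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic thalamocortical connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfc)
```

## The scientific problem

During a provoked migraine-like attack, the coupling between the thalamus and
cortical networks — in particular the salience network (SN), anchored in the
bilateral insulae and dorsal anterior cingulate — is thought to reorganize
phase by phase: antiphase coupling at rest, the thalamus drifting into a
leading role during the prodrome, loss of phase coherence at the attack peak,
and a return to phase-locked behaviour with recovery. `dynfc` implements both
of the analysis arms needed to characterize this from four resting-state BOLD
scans per subject (baseline, prodrome, full-blown, recovery):

* a **static arm**: seed-based correlation analysis (SCA), group inference by
  sign-flip permutation with threshold-free cluster enhancement (TFCE) and
  family-wise error (FWE) control, and a baseline-normalised *relative change
  in functional connectivity* index,
  `rcFC_x = (meanFC_x - meanFC_baseline) / meanFC_baseline`,
  compared across phases by repeated-measures ANOVA with Bonferroni post-hocs;
* a **dynamic arm**: group spatial ICA to isolate the SN, dual-regression
  network time-courses, temporal concatenation of the four scans into one
  session-long signal, and wavelet transform coherence (WTC) between the
  thalamic and SN signals, with Monte Carlo red-noise significance and a
  per-phase circular phase summary.

Because no clinical recordings ship with the package, a synthetic-session
generator plants a known version of exactly this structure, so every stage of
the pipeline can be validated end to end.

## The coherence model

The continuous wavelet transform uses the analytic Morlet mother wavelet
`psi(eta) = pi^(-1/4) exp(i w0 eta) exp(-eta^2 / 2)` with central frequency
`w0 = 6`, evaluated at scales `s_j = s0 * 2^(j * dj)` with `s0 = 2 dt` and
`dj = 1/12`, the largest scale chosen so that the Fourier period
(`4 pi s / (w0 + sqrt(2 + w0^2))`, about `1.033 s`) does not exceed half the
record. Transforms are computed by frequency-domain multiplication after
zero-padding to the next power of two.

Squared coherence is

    R^2(s, t) = |S(s^-1 Wx* Wy)|^2 / ( S(s^-1 |Wx|^2) S(s^-1 |Wy|^2) )

where `S` smooths with a Gaussian of SD `s` in time followed by a boxcar of
0.6 octaves across scale; without `S`, the ratio is identically 1. The phase
is the argument of the smoothed cross-spectrum `S(s^-1 Wx* Wy)`. (A literal
`arg(R^2)` is undefined, since `R^2` is real; the cross-spectrum argument is
the standard quantity and is what the package reports.)

**Sign convention.** The cross-spectrum is `conj(Wx) * Wy`, so the reported
phase is the advance of `y` relative to `x`: positive phase means `x` lags
`y`, `-pi/2` means `x` leads by a quarter cycle. Phases are classified into
the four cardinal classes at `±pi/4` and `±3pi/4`: `in_phase`, `antiphase`,
`x_lags`, `x_leads` (boundary angles fall to the lead/lag classes).

**Cone of influence.** The Morlet e-folding time is `sqrt(2) s`; a cell at
distance `d` seconds from the nearer record edge is uncontaminated up to
scale `d / sqrt(2)`, i.e. period `fourier_factor * d / sqrt(2)`. The cone is
zero at the first and last samples and symmetric about the midpoint.
Significance is never awarded outside the cone.

**Red-noise significance.** Each input is fitted as an AR(1) process (lag-1
sample autocorrelation and innovation SD); `mc_n` independent surrogate
pairs with those parameters are generated, their coherence fields computed,
and in-cone values pooled per scale over time and surrogates. The per-scale
`1 - alpha` quantile is the significance threshold (default `alpha = 0.05`,
`mc_n = 1000`). Scales whose period exceeds the cone everywhere receive an
`NA` threshold; they can never be significant.

## The synthetic generator

`synth_config()` defaults encode the acquisition this package emulates: 5
subjects, 200 volumes per scan at TR 3.01 s, a 24 x 24 x 16 grid of 2.5 mm
isotropic voxels, and a planted 0.05 Hz oscillation — inside the pass band of
the 0.007 Hz high-pass and well below the 0.166 Hz Nyquist limit. Each scan
contains:

* two spherical "thalamus" seed blobs carrying the seed oscillation;
* a two-cluster Gaussian-weighted "SN" map carrying the network oscillation,
  whose phase offset per phase follows the protocol *baseline `pi`
  (antiphase), prodrome `-pi/2` (thalamus leads), full-blown incoherent
  (independent AR(1) of matched power), recovery `0` (in phase)* — a direct
  encoding of the qualitative attack sequence, chosen because it gives the
  recovery test a sharp target;
* independent AR(1) noise per voxel (`phi = 0.4`, a BOLD-like autocorrelation
  at a 3 s TR; innovation SD 1) — spatially independent by default so that
  analytic significance calibration stays valid, with an optional Gaussian
  smoothing switch for spatially correlated noise;
* white-matter (outer shell) and CSF (interior block) compartments, each with
  its own shared AR(1) nuisance signal of amplitude equal to the noise SD.

The coupling amplitude is `coupling_snr` times the stationary noise SD
(default 1). Everything is a pure function of `(config, subject_index)`, so
scans are bit-reproducible.

What the generator does *not* emulate: head motion, scanner drift and
physiological (cardiac/respiratory) cycles, spatial haemodynamic blurring,
between-subject anatomical variability, and registration error. Passing
recovery tests therefore demonstrates that the estimators are correct and
calibrated under the stated noise model, not that the pipeline is robust to
every artefact of real acquisitions.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| high-pass cutoff | 0.007 | Hz | 150 s detrending; raised-cosine ramp from `cutoff/2` to `cutoff`, exact DC removal |
| smoothing FWHM | 5 | mm | per-volume Gaussian; synthetic runs use 0 (blobs are already compact) |
| `w0` | 6 | — | Morlet admissibility and the conventional period/scale factor |
| `dj` | 1/12 | octaves | 12 sub-octaves per doubling; ridge located within one step |
| `mc_n` | 1000 | pairs | Monte Carlo resolution of the 95th percentile |
| `alpha` | 0.05 | — | per-cell significance level |
| seam guard | 5 | samples | cells this close to a concatenation seam are excluded from phase summaries |
| TFCE `E, H, dh` | 0.5, 2, max/100 | — | the convention of FSL-style TFCE; 26-connectivity |
| `coupling_snr` | 1 | — | planted oscillation amplitude / noise SD |

## Numerical and design choices

* **High-pass filter.** A frequency-domain filter with a documented
  raised-cosine response (`highpass_response()`) rather than a running-line
  smoother: the analytic response makes exact oracle tests possible. The
  response applies exactly to the DFT bins of the window; sub-cycle trends
  leak (up to about half their excursion survives), which the documentation
  states rather than hides.
* **Concatenated sessions.** The four scans are joined into one 800-point
  signal and analysed as a single series. The splices introduce artificial
  discontinuities, so phase summaries exclude a 5-sample guard band around
  interior seams.
* **"No coherence" class.** A calibrated 5% test flags about 5% of cells by
  chance, so a segment is classed `none` when its significant fraction does
  not exceed `2 * alpha` (configurable via `none_floor`); requiring literally
  zero significant cells would make the class unreachable at realistic cell
  counts.
* **Sign-flip inference.** Covariates are mean-centered and projected out of
  the subject maps before flipping (reduced-model residualization), the
  one-sample t statistic is recomputed per flip, and the FWE p value uses the
  max-TFCE distribution, one-sided on the positive tail. With `n` subjects
  and `2^n <= n_perm` the null is enumerated exhaustively — with 5 subjects
  the 32 sign flips replace any larger random budget, and the smallest
  attainable corrected p is exactly 1/32. `dh` is fixed from the observed
  map so enhanced statistics are comparable across flips. Voxels with zero
  residual variance are capped at `|t| = 100` (and at exactly zero mean set
  to 0) to keep TFCE finite.
* **ICA model order.** Automatic Bayesian order selection is out of scope;
  order is either a fixed `k` or the smallest PCA subspace explaining 90% of
  variance (capped at 20). The log-cosh contrast is the default; when all of
  its restarts fail to settle — typical when sources are sub-Gaussian, as
  oscillations are — the kurtosis contrast is tried automatically. The
  convergence tolerance defaults to 1e-4 (the value common to the field's
  implementations); much tighter tolerances are unattainable whenever the
  retained subspace includes near-Gaussian directions, whose rotation the
  contrast cannot pin down.
* **Subject averaging.** Per-subject network and seed signals are z-scored
  before averaging so no subject dominates the group coherence input.
* **Sphere ROIs.** A voxel belongs to a sphere when its world-space center
  lies within the radius, boundary inclusive — the simplest convention that
  an exhaustive-enumeration oracle can verify on any grid and affine.
* **meanFC masking.** The per-phase significant mask is `FWE p < alpha` from
  that phase's group statistic; the mean is then taken over the non-zero
  masked voxels of each subject map.
* **Left and right seeds.** Both thalami are always analysed; which seed
  reaches significance is a property of the data, not asserted by the code.

## Problem sizes used by the test-suite and report

The packaged validation works at sizes a laptop handles in minutes: the
coherence property suite uses 200–400-point series; Monte Carlo calibration
uses 300 surrogate pairs and 50 fresh replicate pairs at n = 200; the
planted-protocol recovery runs the full five-subject, four-phase default
session (200 volumes per scan) through preprocessing, extraction,
concatenation, averaging and coherence with 300 surrogates; permutation
inference demonstrations use 5–6 subjects on small grids where the sign-flip
null is exhaustive. These sizes are the package's validation choices; all
are configurable upward.

## Known limitations

* The AR(1) noise model has no spatial autocorrelation by default; real BOLD
  noise is spatially smooth and non-stationary.
* The red-noise test calibrates the per-cell false-positive rate; it does not
  control a family-wise rate across the time–scale plane.
* Dual regression here is the spatial (stage-1) regression only; the
  temporal stage is not needed for the coherence pipeline.
* The NIfTI ingestion path assumes scans are already motion-corrected and
  registered to a common space; no registration is provided.
* Repeated-measures ANOVA assumes sphericity; with four phases and few
  subjects no correction is applied, and the Bonferroni post-hocs are the
  primary guard.
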