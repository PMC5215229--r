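---
title: "Removing baseline drift and cosmic spikes from Raman imaging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing baseline drift and cosmic spikes from Raman imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apri)
```

## The problem

A micro-Raman map records one spectrum per stage position: an `m × n`
matrix with `m` spectra (pixels) and `n` wavenumber channels. Two
contaminants corrupt essentially every such measurement:

* **baseline drift** — a slowly varying additive background from sample
  and substrate fluorescence and from thermal behaviour of the CCD, often
  larger than the Raman bands themselves in lignified plant tissue;
* **cosmic spikes** — narrow (here one to a few channels), strictly
  positive, high-intensity artefacts caused by cosmic rays striking the
  detector, appearing at random positions in random spectra.

Both must be removed before any multivariate analysis: principal
components of raw data describe the contamination, not the chemistry.
`apri()` runs the two corrections in sequence, per pass: airPLS baseline
removal, then PCA most-similar-spectrum despiking.

## Baseline: penalized least squares with adaptive reweighting

The Whittaker smoother balances weighted fidelity against roughness,

$$\min_z\; \sum_i w_i (x_i - z_i)^2 + \lambda \lVert D z\rVert^2,$$

solved through the banded system \((W + \lambda D^\top D)z = Wx\), where
\(D\) is a finite-difference operator. airPLS iterates this smoother:
starting from unit weights, channels that rise above the current fit
(`x >= z`, i.e. peak candidates) get weight zero, channels below keep
`w_i = exp(t |d_i| / |d^-|_1)` with `d = x − z`, `|d^-|_1` the L1 norm of
the negative residuals and `t` the iteration index, pulling the fit onto
the baseline points. Iteration ends when `|d^-|_1 < 0.001 |x|_1` or
after `max_iter = 20` rounds. The corrected spectrum is `x − z`; negative
corrected intensities are kept (clipping is a display concern, and would
bias any later fit).

**Choice of difference order.** The penalty order is configurable (1
or 2) and defaults to 2. This was a genuinely open design point: with the
default `lambda = 1e7` an order-1 penalty has an effective smoothing
length of roughly \(\sqrt\lambda \approx 3000\) channels — three times a
typical 977-channel spectrum — and collapses the fit to a near-constant
(measured baseline-recovery coverage 0.41 versus 0.97 for order 2 on the
synthetic benchmark below). An order-2 penalty at the same `lambda`
smooths over \(\lambda^{1/4} \approx 56\) channels, which is the right
stiffness for fluorescence: broad relative to Raman bands, flexible
enough to follow real background curvature.

**`lambda`** (default `1e7`) trades bias against stiffness: too small
and the "baseline" dives into band clusters; too large and genuine
background curvature is left behind. The default, together with
`max_iter = 20`, is the published operating point of the method and
performs well across the synthetic conditions tested here.

## Despiking: most similar spectrum in component space

Spike removal needs a reference: a spectrum that looks like the
contaminated one but is clean at the affected channels. In an imaging
data set thousands of near-duplicate spectra exist, so the reference is
found in the data itself:

1. **Features.** Eigendecompose the channel correlation matrix of the
   baseline-corrected data; keep the smallest `q` components whose
   cumulative proportion of variance reaches `variance_threshold`
   (default 0.85). Each spectrum's feature is its row of standardized
   projections (scores).
2. **Reference.** The most similar spectrum (MSS) minimizes squared
   Euclidean distance in score space (self excluded, ties to the lower
   index).
3. **Regression.** The spectrum is regressed on its MSS
   (`y ≈ a·y* + b`, closed form); the residual is divided by its
   population standard deviation. The standardization makes detection
   scale-free: multiplying the data set by any positive constant leaves
   the spike mask unchanged.
4. **Threshold.** Standardized residuals of all spectra are stacked into
   a matrix `E0`. Per channel, the positive entries (spikes are strictly
   positive) are sorted in descending order; an abrupt drop — a discrete
   derivative below `deriv_threshold = −1` — separates spike values from
   the bulk. The threshold is placed at the deepest qualifying rank so
   that every larger residual in the channel is flagged; when several
   spikes of different amplitude share a channel, all of them must sit
   above the threshold. A channel with no qualifying drop gets `+Inf`.
5. **Replacement.** Every super-threshold channel becomes a spike
   centre; a window of `spike_window = 41` channels (clipped at the
   edges; overlapping windows merge) is replaced by the fitted reference
   `a·y* + b`. Spikes on this instrument class span up to a few tens of
   channels, so 41 covers all affected channels; unaffected channels are
   returned bit-identical. The replacement window is deliberately much
   wider than the spike itself — the regression-scaled reference keeps
   the local line shape, so over-replacement is cheap and
   under-replacement is not.

**Reference collisions and the second pass.** A reference that carries a
spike at the channels it should repair would copy it in. Two mitigations
are used. Within a pass, a provisional detection round flags candidate
zones; an MSS whose candidate zones overlap the query's is demoted to
the next-nearest spectrum (up to `min(m − 1, 5)` demotions). Across
passes, `apri()` reruns the whole pipeline (`passes = 2` by default):
once the bulk of spikes is removed, the similarity structure changes,
references are re-chosen, and spikes that sat at identical channels in a
spectrum and its pass-1 reference — invisible to the residual — are
exposed. The test suite constructs exactly this adversarial case and
verifies that pass 1 misses it and pass 2 repairs it.

## Numerical choices

* The Whittaker system is solved sparsely (banded Cholesky via the
  Matrix package); it agrees with a dense solve of the same normal
  equations to better than 1e−8 relative error over random instances.
* Zero-variance channels would make the correlation matrix undefined;
  their correlations are set to 0 with a warning (the diagonal stays 1).
  This arises in synthetic edge cases, not in CCD data.
* A constant reference spectrum has no defined regression slope; the fit
  degrades to `a = 0`, `b = mean(y)` with a warning.
* A residual whose standard deviation is below `1e-8` of the spectrum's
  RMS is treated as an exact fit (standardized to zeros): such residuals
  are floating-point noise from an affine-exact reference, and dividing
  by their standard deviation would amplify rounding error into
  spurious unit-scale "residuals".
* Eigenvectors are defined up to sign (and, within degenerate
  eigenspaces, rotation); tests compare against an independent SVD route
  only where eigenvalues are well separated.

## The synthetic generator

`simulate_raman_image()` emulates a poplar cell-wall map measured in
D₂O: Gaussian/Lorentzian bands at the twelve characteristic positions
(cellulose/hemicellulose bands at 1095–1460, lignin aromatics at 1275,
1603, 1656, the CH-stretch envelope at 2889/2940, and the broad D₂O band
at 2490 cm⁻¹), spatial composition patterns (uniform, two-region,
gradient) with per-pixel intensity jitter, a smooth fluorescence-like
baseline (exponential by default; linear, quadratic and sigmoid shapes
available), i.i.d. Gaussian channel noise, and sparse triangular spikes
1–5 channels wide. Defaults are chosen as a realistic operating point:
band scale 200 counts, baseline scale 500 counts (fluorescence larger
than most bands, as in lignified tissue), noise σ = 10 counts (peak
signal-to-noise around 10–20), spikes in 5% of spectra with amplitudes
150–1500 counts (15–150 σ — cosmic events are far brighter than shot
noise). Every component is stored, so the emitted matrix equals
`clean + baselines + noise + spikes` exactly and any correction can be
scored against ground truth.

What the generator does **not** model: Poisson shot noise (additive
Gaussian read noise only, which keeps the analytic truth simple),
detector etaloning, wavenumber miscalibration, and confocal optics
(spatial structure is statistical only). Passing tests therefore
demonstrate correctness of the algorithms under well-specified
contamination, not instrument-specific performance.

## Problem sizes and known limitations

The bundled checks run at desk scale: single spectra of 977 channels for
baseline recovery (10 seeds), 100 × 500 matrices for detection power
(10 seeds), 400 × 300 for clean-map pass-through, and 80 × 300 for the
end-to-end comparison. The pipeline itself is linear in `m` except for
the `m × m` score-distance matrix, the cost the method accepts in
exchange for using the data as its own reference library.

Two limitations are worth stating plainly:

* **Small pools.** The reference-based design assumes many similar
  spectra. Below about 10 spectra the MSS fit is poor and results are
  unreliable; `despike()` refuses `m < 3` and warns below 10.
  Single-spectrum filters are the right tool there.
* **Small-`m` false-positive floor.** The threshold rule fires whenever
  a sorted residual column drops by more than 1 between consecutive
  ranks. For Gaussian residuals the top order-statistic gap shrinks only
  slowly with `m`: the per-channel false-trigger probability is ≈5% at
  `m = 100`, ≈3% at `m = 1000`, ≈2% at `m = 5000`. Each trigger masks a
  41-channel window in one spectrum, so the expected falsely-masked
  channel fraction scales like `2/m`: ≈2% of channels at `m = 100`,
  under 0.5% at `m = 400`, and negligible (≈0.005%) at the
  12,870-spectrum scale of a real map. The false replacements are
  benign — the fitted reference is substituted, typically within noise
  of the truth — but users despiking small data sets should expect this
  floor, and the detection-power check in the test suite records it
  honestly at `m = 100`.
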