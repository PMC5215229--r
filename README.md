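# apri — automatic pre-processing of Raman imaging data

Micro-Raman maps of biological samples (here: poplar wood cell walls
measured in D₂O) arrive as an `m × n` matrix — one spectrum per pixel,
one column per wavenumber channel — corrupted by two contaminants that
wreck any downstream multivariate analysis: slowly varying fluorescence
**baseline drift**, and narrow, strictly positive **cosmic-ray spikes**.
`apri` removes both automatically, using only the spectral features of
the data set itself.

The pipeline runs two stages per pass (two passes by default):

1. **airPLS baseline correction.** Each spectrum `x` gets a baseline `z`
   from iteratively reweighted penalized least squares: `z` minimizes
   `Σ wᵢ(xᵢ − zᵢ)² + λ‖Dz‖²` (a Whittaker smoother, solved sparsely),
   with weights re-derived each iteration — `wᵢ = 0` where `xᵢ ≥ zᵢ`
   (peak points), `wᵢ = exp(t·|dᵢ|/|d⁻|₁)` below — until
   `|d⁻|₁ < 0.001·|x|₁` or 20 iterations. Defaults: `λ = 10⁷`,
   second-order differences.
2. **PCA most-similar-spectrum despiking.** Spectra are embedded by
   their scores on the principal components of the channel correlation
   matrix (components kept until 85% cumulative variance). Each spectrum
   is regressed on its nearest neighbour in score space
   (`y ≈ a·y* + b`); standardized residuals of all spectra are stacked,
   and a per-channel threshold is placed at the abrupt drop
   (sorted-column derivative < −1) that separates spike values from the
   bulk. Flagged channels, widened to a 41-channel window, are replaced
   by the fitted reference. A second full pass catches spikes that sat
   at identical channels in a spectrum and its first-pass reference.

The package also ships a synthetic Raman-image generator with exact
ground truth (poplar band positions, fluorescence baselines, Gaussian
noise, sparse spikes), evaluation metrics (baseline RMSE, spike recall
and precision, channel false-positive rate), principal-component score
maps as a correction diagnostic, delimited and MAT v5 matrix I/O, and a
command-line driver (`inst/scripts/apri`).

## Worked example

```r
library(apri)

sim <- simulate_raman_image(10, 13, n_channels = 400,
                            pattern = "two_region", spike_rate = 0.08,
                            seed = 42)
res <- apri(sim$dataset)
res
#> <apri_result> 130 spectra x 400 channels, 2 pass(es)
#>   pass 1: 1496 channel(s) replaced, q = 68 components
#>   pass 2: 983 channel(s) replaced, q = 57 components

glance(res)
#> # A tibble: 2 × 5
#>    pass     q n_masked_channels mean_baseline_iterations mask_density
#>   <int> <int>             <int>                    <dbl>        <dbl>
#> 1     1    68              1496                     4.99       0.0288
#> 2     2    57               983                     6.02       0.0189

evaluate_correction(res, sim$truth)
#> # A tibble: 1 × 7
#>   baseline_rmse spike_recall spike_precision channel_fpr residual_rmse
#>           <dbl>        <dbl>           <dbl>       <dbl>         <dbl>
#> 1          39.2            1           0.308      0.0326          47.0
#> # ℹ 2 more variables: n_spikes_true <int>, n_masked_channels <int>
```

Reading the numbers: every injected spike was recalled
(`spike_recall = 1`); the corrected data sit at RMSE 47 counts from the
true clean signal, versus 292 for the raw data (the baseline alone is
~500 counts); `q` is the number of principal components needed for 85%
of the variance in each pass. Precision of 0.31 reflects the deliberate
41-channel replacement window around every 1–5-channel spike — wide
replacement with the regression-scaled reference is by design, and the
small-map false-positive rate is discussed in the methods vignette
(`vignettes/apri-methods.Rmd`).

Plotting helpers: `autoplot()` works on data sets, airPLS fits,
despiking results and `pca_score_maps()` output; `tidy()`/`glance()`
turn every result into tibbles.

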