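# msemeg

Multiscale entropy (MSE) analysis for multichannel resting-state
electrophysiological recordings (MEG/EEG), built for group comparisons of
signal complexity: coarse-grained sample entropy across scales,
scale-region summary statistics, phase-randomized surrogate decomposition
of entropy into amplitude and phase components, channel-wise hypothesis
testing with FDR control, and a lasso-regularized LDA classification
protocol with repeated balanced validation splits. A synthetic two-group
cohort generator with known ground truth validates the whole chain end to
end.

Intended users: researchers analyzing resting-state sensor-space
complexity differences between clinical groups, and anyone who needs a
tested, reproducible SampEn/MSE + surrogate pipeline at realistic data
sizes.

## The method in brief

Sample entropy of a series of length $N$ is

$$\mathrm{SampEn}(m, r, N) = -\ln \frac{C^{m+1}(r, N)}{C^m(r, N)},$$

the negative log conditional probability that templates of $m$ points
matching within tolerance $r$ (Chebyshev distance, self-matches excluded)
still match at point $m+1$. Defaults $m = 2$, $r = 0.2 \times$ SD. The
MSE curve evaluates SampEn on coarse-grained series
$y^{(\tau)}_j = \tfrac{1}{\tau}\sum_{i=(j-1)\tau+1}^{j\tau} x_i$; scale
$\tau$ corresponds to an equivalent sampling rate $f_s/\tau$ and detects
frequencies up to $f_s/(2\tau)$. Scale regions are summarized by
$\kappa$ (mean SampEn over the region) and groups compared by
$\Delta\kappa = 2(\kappa_A - \kappa_B)/(\kappa_A + \kappa_B)$.
Phase-shuffled surrogates isolate the nonlinear (phase) component
$\kappa_\mathrm{nlc} = \kappa_\mathrm{psf} - \kappa_\mathrm{org}$.
See the methods vignette (`vignettes/multiscale-entropy-methods.Rmd`)
for the full account.

## Worked example

```r
library(msemeg)

# a small two-group cohort: 8 + 8 subjects, 16 channels, 30 s at 300 Hz;
# patients carry a steeper (entropy-raising) spectral slope medially
cfg <- cohort_config(n_per_group = 8, n_channels = 16, fs = 300, duration = 30,
                     effect = list(slope = 0.3), effect_region = "medial",
                     seed = 42)
cohort <- generate_cohort(cfg)
cohort$recordings[[1]]
#> <recording> sub001 (patient): 16 channels x 9000 samples @ 300 Hz

# zero-phase 1-80 Hz band-pass, then entropy curves (original +
# phase-shuffled surrogate) on a reduced grid
filtered <- lapply(cohort$recordings, apply_filters,
                   spec = filter_spec(bandpass = c(1, 80), notch = numeric(0)))
grid <- c(4L, 12L, 22L, 36L, 48L, 80L)
curves <- cohort_mse(filtered, grid = grid, seed = 42)
head(curves, 3)
#> # A tibble: 3 × 6
#>   subject group   channel variant   tau sampen
#>   <chr>   <chr>   <chr>   <chr>   <int>  <dbl>
#> 1 sub001  patient CH001   org         4   1.67
#> 2 sub001  patient CH001   org        12   1.72
#> 3 sub001  patient CH001   org        22   1.63

# kappa over the full 4-80 scale range, nonlinear component appended
regions <- tibble::tibble(region = "full", x1 = 4L, x2 = 80L)
ktab <- kappa_table(curves, regions)

# channel-wise Welch tests with BH correction
cmp <- channelwise_tests(ktab, variant = "org", region = "full")
```

This prints:

```
significant channels: 6 of 16 (p < 0.05), 5 after FDR
mean delta-kappa: medial +0.089, periphery +0.002
```

The configured effect sits on the 6 medial channels and that is where
the significant channels and the positive normalized group difference
(Δκ) concentrate; peripheral channels stay at chance. `mse_feature_table()`
and `psd_band_features()` turn curves and spectra into the 168 MSE / 180
band-power features per subject, and `multirealization_eval()` runs the
lasso-LDA protocol with balanced validation truncation, reporting
accuracy mean ± SD across splits, pooled ROC/AUC and the selected
features.

## The analysis workflow

`analysis/` holds numbered drivers that run the bundled desk-scale study
(20 + 20 subjects, 64 channels, 60 s at 300 Hz) and write their tables
under `results/`:

1. `01_simulate.R` — cohort, sensor layout, ground truth.
2. `02_entropy_curves.R` — filtered MSE curves, original + surrogate
   (the expensive stage, a few minutes).
3. `03_group_statistics.R` — kappa tables, channel-wise tests, area and
   medial/periphery summaries, amplitude/phase balance.
4. `04_classification.R` — feature tables, lasso-LDA report, permutation
   chance control.

Raw series are never persisted; every stage regenerates them
bit-identically from the seed.

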