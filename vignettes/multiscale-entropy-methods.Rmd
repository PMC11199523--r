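---
title: "Multiscale entropy analysis of multichannel resting-state recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy analysis of multichannel resting-state recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The method

## Sample entropy and the multiscale curve

Sample entropy (SampEn) measures the regularity of a time series. Two
points are indistinguishable when their absolute difference is within a
tolerance $r$; two templates of $m$ consecutive points match when every
pair of corresponding points is indistinguishable (a Chebyshev distance
criterion). With $C^m$ the number of matching template pairs of length $m$
over the first $N - m$ templates, self-matches excluded,

$$\mathrm{SampEn}(m, r, N) = -\ln \frac{C^{m+1}(r, N)}{C^{m}(r, N)},$$

the negative log of the conditional probability that templates matching
for $m$ points still match at point $m + 1$. We use the common defaults
$m = 2$ and $r = 0.2$ in units of the series' standard deviation, which
sit in the $m \in \{1, 2\}$, $r \in [0.1, 0.25]$ range that the entropy
literature has found statistically stable for short noisy biological
series.

The multiscale entropy (MSE) curve evaluates SampEn on progressively
coarse-grained copies of the series. Coarse-graining at scale factor
$\tau$ averages non-overlapping windows of $\tau$ samples,

$$y^{(\tau)}_j = \frac{1}{\tau} \sum_{i = (j-1)\tau + 1}^{j\tau} x_i,
\qquad 1 \le j \le \lfloor N / \tau \rfloor,$$

so a 4-minute record at 600 Hz retains 1200 samples at $\tau = 120$.
Coarse-graining is a form of downsampling: scale $\tau$ corresponds to an
*equivalent sampling rate* $\mathrm{ESR} = f_s / \tau$ and, by Nyquist,
can reflect signal frequencies up to $f_s / (2\tau)$. At 600 Hz, scales 4
and 10 correspond to sampling at 150 Hz and 60 Hz and to detectable
frequencies up to 75 Hz and 30 Hz.

Two conventions matter and are fixed here (both configurable):

* the tolerance is resolved **once**, against the SD of the scale-1
  series, and reused for every scale. Re-normalizing per scale would hide
  exactly the variance loss that the multiscale curve is designed to
  expose;
* point matches use $\le r$ (the Richman–Moorman convention). A strict
  $<$ comparison is available as `sampen_params(strict = TRUE)`; for
  continuous data the two differ only on ties of measure zero.

When no template matches exist (constant series, or very tight
tolerance), SampEn is undefined: the package returns `NA` and downstream
reductions drop and renormalize rather than silently zeroing.

## Scale regions and kappa

The entropy-vs-scale curve is summarized per *scale region*
$[x_1, x_2]$ by its mean height,

$$\kappa = \frac{1}{x_2 - x_1} \int_{x_1}^{x_2} \mathrm{SampEn}(x)\,dx,$$

computed as a trapezoidal integral on the available integer grid divided
by the span the defined grid points actually cover (undefined points are
excluded and the span renormalized). The five default regions in
scale-factor units are full 4–80, high 48–70, mid 28–36, low 16–22, and
very-low (VLS) 4–12. One printed bound in the source table for the low
region's recoverable-frequency column (33.75 Hz) is inconsistent with the
Nyquist rule ($f_s / (2 \cdot 16) = 18.75$ Hz at 600 Hz); the package
follows the Nyquist rule and does not reproduce that entry.

Group contrasts use the normalized difference

$$\Delta\kappa = 2\,\frac{\kappa_A - \kappa_B}{\kappa_A + \kappa_B},$$

which is bounded by $(-2, 2)$ whenever both group means are positive; the
same formula serves per-scale SampEn differences.

## Phase-shuffled surrogates and the nonlinear component

A phase-randomized surrogate keeps the amplitude spectrum of a series
bin-for-bin but replaces the phases of the positive frequencies with iid
uniform draws (conjugate-mirrored; DC and the even-length Nyquist bin
stay real). Surrogates therefore have the same linear (amplitude/PSD)
structure but none of the phase-dependent structure, such as long-range
temporal correlations of oscillatory envelopes. The entropy attributable
to phase structure is the residue

$$\kappa_{\mathrm{nlc}} = \kappa_{\mathrm{psf}} - \kappa_{\mathrm{org}},$$

with group contrasts $\Delta\kappa_{\mathrm{nlc}}$ (difference of group
means) and its normalized form. To compare the amplitude/phase balance of
two sensor areas, per participant and area the channel-wise normalized
differences (each participant against the other group's channel means)
are averaged into $K_{\mathrm{psf}}$ and $K_{\mathrm{nlc}}$, combined as
$R = K_{\mathrm{psf}} / (K_{\mathrm{psf}} + K_{\mathrm{nlc}})$, and the
two areas contrasted by $R' = R_1 / R_2$ and $\Delta R = R_1 - R_2$ with
Welch t-tests between groups. The per-participant reading of $K$ is the
default because the statistic is defined "for each participant"; a
group-level alternative is available (`per_participant = FALSE`) since
the text permits either reading. One realization per subject and channel
is the default (matching the singular "a phase-shuffled signal");
averaging over `n_realizations` surrogates is available to reduce
surrogate noise.

## Channel-wise statistics

Each channel is tested with a Welch (unequal-variance) two-sample t-test
on $\kappa$; the source analysis names only a "t-test" but compares
unbalanced groups (49 vs 98), for which the Welch form is the robust
choice. Benjamini–Hochberg adjustment across channels yields q-values;
channels with zero variance in both groups are flagged and excluded from
the FDR family rather than entering with undefined statistics. Tests are
two-sided with 0.05 thresholds for both p and q, all configurable.

## Features and classification

Per channel, seven MSE features: $\kappa$ over the five scale regions,
the curve's peak value, and the scale of the peak (smallest scale on
ties). The four summary statistics (mean, max, min, SD) of each feature
across the channels of each binary sensor region (medial
parieto-occipital vs periphery) give $7 \times 2 \times 4 = 56$ features
per signal variant and 168 over the three variants (original, surrogate,
nonlinear component). The printed description overlaps its
"averaged across channels" and "four statistics per ROI" steps; the
implementation takes the four statistics across channels within each ROI,
with the ROI mean serving as the averaged feature — the only reading that
reproduces every printed count (14, 56, 168).

Band-power features use a Welch spectrum (2-s Hann segments, 50% overlap
— unstated in the source, standard practice, configurable) and the five
canonical bands δ 0.5–4, θ 4–7.5, α 7.5–12.5, β 15–30, γ 30–40 Hz, kept
verbatim including the 12.5–15 Hz gap. Band power is normalized by the
total 0.5–40 Hz integral per channel. Averaged over 9 ROIs (6 anatomical
areas, 2 binary regions, all sensors) this gives 45 base features and,
with the four statistics, 180 values per subject. (The source's summary
table lists 240 PSD features where its own text derives 180; the text's
derivation is implemented.)

Classification follows the "LDA with lasso" recipe: at each penalty
$\lambda$ (default grid 0.02–0.4), an L1-penalized logistic fit on
standardized training features selects the nonzero-weight subset, and an
ordinary linear discriminant is fit on that subset. The exact selection
estimator is not specified in the source; penalized logistic regression
is the standard sparse linear choice and the component is pluggable.
Evaluation uses repeated stratified train/validation splits (default 500,
70/30 — the multi-realization details live in supplementary material not
available here, so both are configuration), with the validation majority
class randomly truncated to the minority count so that chance is exactly
50%. Standardization parameters are fit on the training fold only. The
pooled validation scores at the best penalty give the ROC and AUC
(Mann–Whitney form, ties counted ½) and a Youden-J operating point; the
source's printed sensitivity/specificity pairs read as sensitivity /
false-positive-rate and are not used as references. With exactly
duplicated features, coordinate-descent lasso splits weight across the
copies rather than dropping one; `prune_collinear()` (|r| > 0.95,
preferring the mean-statistic variant) is provided for minimal-subset
searches where that matters.

# The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
not MEG physiology:

* per-channel $1/f^{\beta}$ background via frequency-domain amplitude
  masking of white Gaussian noise, with Gaussian band bumps (default α at
  10 Hz, weaker β at 20 Hz) — giving exact control of the amplitude
  component that dominates the group effect;
* phase-coupled structure from a lag-smoothed quadratic self-coupling,
  followed by re-imposition of the original amplitude spectrum, so the
  injected nonlinearity is exactly what phase randomization destroys and
  the power spectrum is untouched;
* a two-group cohort: controls carry baseline parameters (default slope
  1.0 medial, 1.2 periphery); patients receive offsets inside a
  designated effect region (default slope +0.2 on medial channels).
  Direction matters here: over the analyzed scales (4–80, tolerance fixed
  at scale 1), a steeper 1/f background retains more variance under
  coarse-graining and so carries *higher* sample entropy and kappa —
  a positive slope offset is the entropy-raising direction, and the
  lower medial baseline gives the medial region its lower kappa. This
  holds for the band-passed signal: the 1-80 Hz filter removes the
  ultra-slow content that would otherwise dominate the scale-1 SD (and
  hence the tolerance) of steep-slope channels and invert the contrast;
* between-subject variability as a per-subject slope offset (SD 0.05,
  shared across channels) — enough to make subject-level statistics
  meaningful while keeping the configured effect (−0.2) clearly
  detectable;
* a 64-channel disc layout with the inner 24 sensors labelled medial
  parieto-occipital, a desk-scale stand-in for the 273-sensor helmet
  (real layouts load from CSV);
* one master seed; every subject, channel, surrogate and split seed is
  derived deterministically from it, so cohorts are bit-reproducible.

Default geometry follows the study conditions: 600 Hz, 240 s, and the
unbalanced 49 + 98 group sizes. What the generator does **not** emulate:
artifacts (blinks, cardiac), inter-channel correlation from volume
conduction, nonstationarity, or any biophysical forward model. Passing
the recovery tests therefore shows that the pipeline detects the kinds of
spectral and phase structure it targets — not that it reproduces clinical
effect sizes on real MEG, which are excluded here because the source
dataset is available only on request.

# Numerical choices

* **SampEn kernel**: compiled (Rcpp) lag-scan with run-length counting —
  a flat $O(N^2)$ per scale with sequential memory access. At the sizes
  used here (N ≤ 20,000) this outruns the need for cleverer
  sorted/vectorized counting schemes while remaining an exact count; the
  brute-force $O(N^2)$ double loop survives as the test-suite oracle.
* **ESR formula**: the source's printed form ("ESR$(f_s) = 1/f_s$") is
  dimensionally inconsistent with all its worked examples; $f_s / \tau$
  is implemented, as the examples dictate.
* **Default scale grid**: the working range is described as 38 scale
  factors from 4 to 120 without spacing; the default is 38 approximately
  log-spaced unique integers over that range (dense where the curve
  bends, sparse at high scales), overridable by any explicit integer
  list.
* **Filtering**: zero-phase forward–backward Butterworth band-pass
  (order 6) plus 2nd-order band-stop notches at 60 Hz harmonics below the
  upper band edge. Zero phase matters because phase distortion would leak
  into the surrogate-based phase-component analysis. Order 6 (rather than
  the more common 4) makes the stop-band contract — > 20 dB one third of
  an octave outside the band — hold under forward–backward application.
  The source states both a 1–80 Hz band-pass and a 0.61 Hz high-pass
  without composition order; the band-pass alone is the default and the
  high-pass is exposed as an option.
* **Degenerate inputs**: zero-variance series, empty template-match
  counts, zero denominators in normalized differences, and zero-variance
  channels all yield flagged `NA` values that propagate explicitly.
* **Problem sizes**: the bundled validation study uses 20 + 20 subjects,
  64 channels, 60 s at 300 Hz, a 9-point scale grid (4–80, at least two
  points per region), 200 classifier realizations over an 8-point penalty
  grid, and 50 null cohorts of 10 + 10 subjects × 24 channels (8 s at
  150 Hz, scales 2–8). These sizes keep a full run in the ten-minute
  range on one desktop CPU while leaving all recovery margins wide.
* **Chance control**: a single label permutation of 40 subjects can land
  close to the true grouping or its inversion and be genuinely learnable
  (the permutation distribution of validation accuracy has an SD of
  several points); the reported chance level is therefore a mean over 20
  permutations with the penalty fixed at the true-label selection.

# Known limitations

* The synthetic cohort draws channels independently; spatially correlated
  noise (volume conduction) would lower the effective number of
  independent channels in the FDR family.
* $\kappa$ on the reduced 9-point grid is a coarse trapezoid; the
  dense-vs-coarse grid test bounds the discretization error at ~1% for
  smooth curves, but sharply peaked curves would need a denser grid.
* The lasso-LDA default is one specific reading of "LDA with lasso
  regularization"; alternatives (sparse discriminant analysis, penalized
  LDA) plug into the same evaluation loop but are not bundled.
* Storage uses plain-text containers (TSV matrices + JSON/CSV sidecars);
  they round-trip exactly and keep every artifact diffable and
  greppable, at the cost of size for long recordings.
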