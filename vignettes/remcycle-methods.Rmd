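---
title: "Modelling ultradian REM-sleep timing with remcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ultradian REM-sleep timing with remcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(remcycle)
library(dplyr)
```

## The model

Rodent sleep alternates between REM and NREM episodes on an ultradian time
scale. A long-standing observation is that the duration of a REM episode
predicts the amount of NREM sleep that follows before the next REM episode
("REM sleep homeostasis"), but the relationship is complicated by
*sequential* cycles — clusters of closely spaced REM episodes separated by
only brief NREM interludes.

remcycle models this with a **conditional lognormal Gaussian mixture**. Let
`rem_pre` be the duration (s) of the REM episode opening a sleep cycle, and
`|N|` the total NREM time (s, microarousals included) until the next REM
episode. Conditional on `rem_pre` = x,

$$P(\ln|N| \mid x) \;=\; k_{long}(x)\, f\!\big(\mu_{long}(x), \sigma^2_{long}(x)\big)
  \;+\; k_{short}(x)\, f\!\big(\mu_{short}(x), \sigma^2_{short}(x)\big),$$

where \(f\) is the normal density, \(k_{short} = 1 - k_{long}\), and
\(k_{long}(x) = \min(a\ln(x+b)+c,\,1)\) is clamped because it is a
probability. Each of the five parameters is a *curve* over `rem_pre` —
either logarithmic \(y = a\ln(x+b)+c\) with \(b \ge 0\), or linear
\(y = ax+b\) — so the whole model has at most 15 coefficients.

Fitting proceeds in two stages:

1. **Per-bin mixtures** (`fit_bin_mixtures()`): cycles with
   `rem_pre` < 240 s are grouped into 30 s bins
   (`[0,30), ..., [210,240)`), and a two-component Gaussian mixture is
   fitted to `ln|N|` in each bin by expectation–maximization. Bins at or
   beyond 150 s are unimodal and get a single Gaussian (`k_long` = 1).
2. **Parameter curves** (`fit_parameter_curves()`): for each parameter,
   both curve kinds are fitted by least squares (bounded
   Levenberg–Marquardt for the logarithmic kind, multi-started from
   \(b_0 \in \{0, 1, 10, 100\}\)) and the lower-RSS kind is kept. The
   `k_long` curve uses only the leading bins (6 by default; 4 is
   appropriate for sparse dark-phase data) because the weight saturates
   at 1.

Everything downstream derives from the fitted object: the conditional
density and CDF (`mixture_pdf()`, `mixture_cdf()`), a sampler
(`sample_N()`), the sequential/single taxonomy, the refractory period, and
the REM-propensity statistics.

### Domain of validity

The taxonomy requires the weighted short and long component densities to
intersect strictly between their means. `compute_domain_min()` scans the
2.5 s epoch grid for the smallest `rem_pre` where that holds and stores it
as `domain_min`; below it, cycles are labelled `"undefined"` rather than
forced into a class. In published mouse data this minimum came out at
7.5 s (light phase) and 12.5 s (dark phase); for the synthetic ground
truth shipped here it is 15 s (see below).

### Sequential vs single cycles, refractory period, propensity

* `intersection_threshold()` solves
  \(k_{short} f_{short}(z) = k_{long} f_{long}(z)\) in closed form (the
  log of the equality is a quadratic in \(z\)) and returns the root inside
  \((\mu_{short}, \mu_{long})\). A cycle with \(\ln|N|\) below it is
  *sequential*, otherwise *single*; this is equivalent to choosing the
  component with the larger weighted density. If, under extrapolated
  curves, the quadratic has no interior root, `classify_cycles()` falls
  back to that posterior comparison directly. With two interior roots the
  larger one is used — it is where dominance switches from the short to
  the long component as \(\ln|N|\) grows.
* `refractory_threshold()` is the 1st percentile of the long component,
  \(\exp(\mu_{long} + \sigma_{long} z_{0.01})\) seconds: the initial span
  of a single cycle during which a NREM→REM transition is extremely
  unlikely. The normal quantile comes from `qnorm()`, not a hard-coded
  constant.
* `propensity_at_rem_onset()` evaluates the model CDF at the cycle's own
  `|N|` — the modelled probability of having re-entered REM by the time
  the animal actually did. Because the published correlation analyses of
  REM-propensity concern single cycles, a `long_only` switch evaluates
  the long-component CDF instead; both are provided since the source
  analyses do not state which CDF is meant.

### Goodness of fit

The KS test is invalid when the tested distribution was fitted to the same
sample, so `lilliefors_ks()` applies a Monte-Carlo (Lilliefors-style)
correction: draw `n_sim` samples of the original size from the fitted
mixture, *re-estimate* the mixture on each, and collect the KS statistics
against the re-fitted CDFs. The observed statistic is compared with the
95th percentile of this null distribution. Re-estimation is the essence of
the correction — without it the test is conservative — but `refit = FALSE`
reproduces the literal uncorrected reading. The re-fits use a lighter EM
control (3 restarts, tolerance 1e-6) than the primary fit because
thousands of them run per test; the calibration check below shows this is
sufficient.

## Numerical choices

* **EM**: initialisation by a median split plus 20 random quantile-split
  restarts; convergence at a log-likelihood increment below 1e-8
  (500-iteration cap); component variances floored at 1e-6 to prevent
  collapse; the "long" label is assigned to the larger-mean component
  after fitting (label-switching guard). Degenerate (constant) samples
  are rejected. The per-iteration log-likelihood is monotone and the fit
  matches `mclust` and a brute-force grid MLE in the tests.
* **Curve fits**: bin x-coordinates default to the *mean* `rem_pre` of
  the bin's cycles rather than the bin midpoint. REM-episode durations
  are far from uniform within a 30 s bin (short episodes are much more
  frequent), and assigning the estimate to the midpoint visibly biases
  the recovered curves at the low end of the domain; the within-bin mean
  is unbiased regardless of the duration distribution. `bin_x =
  "midpoint"` restores the midpoint convention.
* **Kind selection**: the logarithmic family contains near-affine curves
  (large \(b\)), so with noisy bins the RSS comparison between kinds is
  close to a tie whenever the truth is gentle; the *fitted function*
  is stable even when the kind label is not, and tests assert function
  values, not labels.
* **Clamps**: `k_long` is clamped to \([0, 1]\) (the upper clamp is part
  of the model definition; the lower clamp reflects that weights are
  probabilities), and standard deviations are floored at 1e-6 when
  curves are evaluated. Evaluation beyond the fitted 240 s range is
  allowed with an extrapolation warning.
* **Epoch grid**: 2.5 s epochs are authoritative; all durations are
  epoch counts times the epoch length, with no sub-epoch interpolation.

## Sleep staging and EEG analyses

`compute_scoring_features()` builds a spectrogram from consecutive FFTs
over sliding half-overlapping 5 s Hann windows (2.5 s resolution) and
integrates the *scoring* bands: δ 0.5–4, θ 5–12, σ 12–20, high-γ 100–150,
EMG 50–500 Hz. `classify_states()` thresholds each feature at its temporal
mean (mean + 1 SD for EMG and θ/δ): REM = high θ/δ, low EMG, low δ;
NREM = (high δ, low θ/δ, low EMG) or (low EMG, low δ, high σ);
wake = (low δ, high EMG) or any high-γ bin not already REM. When several
rules fire, REM takes precedence over NREM over wake (the REM rule is the
most specific conjunction); unmatched bins inherit the previous label,
the first defaulting to wake. Thresholds are data-relative, so staging is
invariant to channel rescaling. The final epoch, which has no complete 5 s
window of its own, repeats the last computed feature row so features align
one-to-one with epochs.

Spectral *analyses* use different, deliberately non-identical bands
(δ 0.5–4.5, θ 5–9.5, σ 10–15 Hz; `analysis_bands`): `welch_psd()`
averages 3 s half-overlapping Hann periodograms (1/3 Hz resolution),
`band_power()` integrates them with a midpoint Riemann sum over cells
whose midpoints fall in the half-open band \([lo, hi)\) — half-open so
adjacent bands never double count.

`detect_spindles()` implements the two-criterion sigma-burst detector:
600 ms windows at 100 ms steps; criterion 1, the largest local spectral
maximum in 10–16.67 Hz exceeds the 96th percentile of all such maxima over
the recording; criterion 2, that peak exceeds half the peak power below
10 Hz; adjacent flagged bins merge, gaps under 300 ms fuse, events of at
most 200 ms are dropped, and an event survives only if its spectral peak
frequency lies in the sigma band for at least half its bins. Detection is
restricted to NREM (incl. microarousal) epochs by default, since spindle
rates are reported per minute of NREM; `restrict_nrem = FALSE` lifts the
restriction. The percentile threshold is computed once per recording, so
isolated short recordings with little sigma activity will still flag their
top few percent of bins — false-positive behaviour is therefore a property
of a realistically composed recording, which is how the tests measure it.

## The synthetic ground truth

No public recordings accompany the modelled data set, so the package
ships a generator whose defaults *are* the study conditions used by the
test-suite (`default_ground_truth()`):

* Conditional model (light phase): `k_long` logarithmic, reaching 0 at
  13 s and 1 at 150 s; `mu_long` linear-increasing (5.4 → 6.6 ln-s over
  the domain); `mu_short` and `sigma_long` gentle logarithmics;
  `sigma_short` linear-decreasing. The resulting `domain_min` is 15 s.
  These curves reproduce the published qualitative trends (weight and
  long-mean increasing, spreads decreasing, weight saturating at 150 s),
  keep the refractory threshold between one and three times `rem_pre`
  through the mid-range, and keep the CDF at 2000 s above 0.99 across the
  domain. The coefficients are fixture constants — the study's fitted
  values are not printed in its text — and were chosen so that the binned
  estimator is *consistent with its own generator*: every curve is gentle
  within a 30 s bin (steep within-bin variation biases first-bin
  estimates), and the domain minimum coincides with the first bin's
  x-coordinate so curve recovery is interpolation, never extrapolation.
* REM-duration law: gamma (shape 1, scale 70 s) truncated to
  [7.5, 240] s — mean near 70 s, and no episodes below the three-epoch
  scoring minimum used in practice.
* Wake structure: 43% of inter-REM intervals are uninterrupted;
  otherwise a geometric number of wake episodes with lognormal durations
  above the 20 s microarousal threshold. Microarousal bouts (1–8 epochs)
  are carved out of the NREM budget at 0.6/min, so `|N|` is conserved
  after MA scoring. Each wake or MA block occupies its own slot between
  NREM epochs, so distinct runs never merge.
* Signals: per-state band-limited noise over a pink floor (NREM high δ;
  REM high θ, low δ, low EMG; wake high EMG and γ), 1000 Hz, with
  Hann-enveloped 11–15.5 Hz spindle packets (0.5–1.5 s) injected into
  NREM at 3/min and annotated. The spindle amplitude and background σ
  gain put the detector near its published operating point (high
  recall, few-percent false detections).

What the generator does **not** emulate: biophysically realistic EEG
(no 1/f knee, no artifacts, no inter-animal variability), state
transitions with realistic boundary ambiguity, REM_post effects of
propensity (off by default so propensity analyses can be tested under the
null), or circadian drift within a recording. Passing tests therefore
demonstrate the *estimators* are correct under the model's own
assumptions, not that mouse EEG meets those assumptions.

## Problem sizes used by the validation suite

The automated checks run at desk scale, chosen to finish in minutes on
one CPU: 5000 cycles for mixture-fit closure; 20 samples of n = 200 for
the EM-vs-grid comparison; a 50 × 200 grid for the distribution
contracts; 10⁴ points for the classification oracle; 200 null data sets
with 200 Monte-Carlo rounds each for the Lilliefors calibration (the
published analysis used 10,000 rounds; the rejection rule is identical);
6 h of hypnogram for pipeline closure; and 2 h recordings for staging
(≥ 90% epoch agreement) and spindle detection (~200 annotated bursts,
recall ≥ 0.85, false detections ≤ 10%).

## A worked example

```{r example}
gt <- default_ground_truth()
sim <- generate_hypnogram(gt, total_duration = 6 * 3600, seed = 1)
hyp <- score_microarousals(sim$hypnogram, ma_threshold = 20)
head(extract_cycles(hyp))

# fitting needs a pooled, multi-recording-sized cycle set: a single
# night's ~60 cycles cannot fill the eight REM-duration bins
cycles <- generate_cycles(gt, 3000, seed = 1)
bins <- suppressWarnings(fit_bin_mixtures(cycles))
model <- fit_parameter_curves(bins, phase = "light")
model

tidy(model)
glance(model)

annotated <- classify_cycles(cycles, model)
count(annotated, label)
```

```{r plots}
plot_parameter_curves(model)
autoplot(model)
plot_propensity_cdf(model)
```

## Known limitations

* The two-stage fit (bins, then curves) is the published procedure, not
  a joint maximum-likelihood fit; uncertainty from stage one is not
  propagated into stage two. The bootstrap comparison
  (`bootstrap_phase_comparison()`) quantifies the combined sampling
  variability instead.
* With fewer than ~10 cycles a bin is skipped, and with sparse data the
  curve fits can extrapolate poorly below the first usable bin; the
  model reports its `domain_min` and refuses evaluation below it rather
  than guessing.
* Mixture MLEs with a vanishing component weight are inherently
  unstable; the EM guards (variance floor, restarts, label ordering)
  mitigate but cannot remove this.
* The spindle detector's tunables (96th percentile, peak ratio ½,
  300 ms gap, 200 ms minimum) are taken as given from their published
  optimisation; no annotated corpus is shipped to re-optimise them.
* Bootstrap resampling treats cycles as exchangeable units; recordings
  or animals as resampling units are not implemented.
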