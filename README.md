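# remcycle

Probabilistic modelling of the ultradian timing of REM sleep in rodent
recordings.

## The problem

Mouse sleep alternates between REM and NREM episodes every few minutes.
How much NREM sleep follows a REM episode — and how soon the next REM
episode can begin — depends on how long the preceding REM episode lasted.
The dependence is not a simple regression: inter-REM intervals are a
mixture of *short* intervals (closely spaced "sequential" REM cycles) and
*long* intervals that begin with a *refractory period* during which
NREM→REM transitions are extremely unlikely. remcycle is for sleep
physiologists who score rodent EEG/EMG into hypnograms and want a
statistical model of that structure.

## The model

For a sleep cycle with preceding REM duration `REM_pre = x` (s) and total
inter-REM NREM amount `|N|` (s, microarousals included), remcycle fits

    P(ln|N| | x) = k_long(x) · N(mu_long(x), sigma_long(x)^2)
                 + k_short(x) · N(mu_short(x), sigma_short(x)^2)

with `k_short = 1 − k_long` and `k_long(x) = min(a·ln(x+b)+c, 1)`. The
five parameters are smooth curves over `REM_pre` (logarithmic
`a·ln(x+b)+c` with `b ≥ 0`, or linear `a·x+b`), estimated in two stages:
per-30 s-bin two-component mixtures of `ln|N|` by EM, then least-squares
curve fits with the lower-RSS kind kept. Derived from the fitted model:

* the sequential/single cycle taxonomy (threshold at the intersection of
  the weighted component densities);
* the refractory threshold `exp(mu_long + sigma_long·z_0.01)`, the 1st
  percentile of the long component;
* REM propensity, the model CDF evaluated at the cycle's own `|N|`;
* a Lilliefors-corrected Monte-Carlo KS goodness-of-fit test;
* bootstrap comparison of parameter curves between conditions
  (light vs dark phase).

Around the model the package provides hypnogram I/O and sleep-cycle
segmentation with microarousal scoring, automatic sleep staging from
EEG/EMG, Welch spectral densities, band powers and a sigma-burst sleep
spindle detector, plus a synthetic-data generator (cycles, hypnograms,
and 1000 Hz EEG/EMG signals with annotated spindles) that stands in for
the unreleased recordings and gives every stage a ground truth to test
against.

## Worked example

A hypnogram (one night here; real studies pool thousands of cycles from
many recordings) is scored for microarousals and segmented into sleep
cycles:

```r
library(remcycle)

gt  <- default_ground_truth()                       # study-condition generator
sim <- generate_hypnogram(gt, total_duration = 6 * 3600, seed = 1)
hyp <- score_microarousals(sim$hypnogram, ma_threshold = 20)
extract_cycles(hyp)[1:3, c("rem_pre", "inter_rem", "n_total", "w_total",
                           "wake_episode_count", "rem_post")]
#>   rem_pre inter_rem n_total w_total wake_episode_count rem_post
#> 1    10       260      95       165                  3     47.5
#> 2    47.5      37.5    37.5       0                  0     40
#> 3    40        55      55         0                  0     15
```

Fitting needs a pooled cycle set (a single night's ~60 cycles cannot fill
the eight REM-duration bins), so here the cycle-level generator stands in
for a multi-recording data set:

```r
cycles <- generate_cycles(gt, 3000, seed = 1)
bins   <- fit_bin_mixtures(cycles)                  # EM per 30 s REM_pre bin
model  <- fit_parameter_curves(bins, phase = "light")
model
#> Conditional Gaussian mixture model of ln(|N|) given rem_pre
#>   phase: light   domain: [12.5, 240) s
#>   k_long      (logarithmic) 0.3965 * ln(x + 0) + -0.9987
#>   mu_long     (logarithmic) 7.198 * ln(x + 1275) + -46.17
#>   mu_short    (linear)     0.002712 * x + 3.927
#>   sigma_long  (logarithmic) -0.1656 * ln(x + 139) + 1.275
#>   sigma_short (linear)     0.0001478 * x + 0.3727
```

The printed curves say, for example, that at `REM_pre = 60 s` the long
component has weight `k_long(60) ≈ 0.63` — about 37% of cycles after a
60 s REM episode are sequential — with mean `exp(mu_long(60)) ≈ 278 s`
of NREM before the next REM episode. The model's domain starts at
12.5 s, the smallest `REM_pre` where the two weighted components
intersect between their means.

```r
annotated <- classify_cycles(cycles, model)   # sequential / single / undefined
dplyr::count(annotated, label)
#>   label          n
#> 1 sequential  1110
#> 2 single      1682
#> 3 undefined    208

refractory_threshold(model, c(60, 120, 180)) # seconds of NREM, ~2x REM_pre
#> [1] 110.2 167.3 245.6

mixture_cdf(model, 60, c(100, 300, 2000))    # P(next REM within |N| s NREM)
#> [1] 0.3451 0.7342 1.0000
```

Staging and spindle detection run on signals (real or generated):

```r
sig <- generate_signals(sim$hypnogram, gt, seed = 2)
staged <- classify_states(compute_scoring_features(sig$recording))
spindles <- detect_spindles(sig$recording$eeg_prefrontal, fs = 1000,
                            h = sim$hypnogram)
event_rate(spindles$onset, sim$hypnogram, "N")   # spindles per NREM minute
```

`tidy()`, `glance()` and `augment()` methods summarise fitted models, and
`autoplot()` / `plot_parameter_curves()` / `plot_propensity_cdf()` draw
the standard figures.

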