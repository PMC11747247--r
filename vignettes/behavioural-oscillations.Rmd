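---
title: "Detecting behavioural oscillations with surrogate-based spectral inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting behavioural oscillations with surrogate-based spectral inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavosc)
```

## The problem

In a dense-sampling psychophysics paradigm, a brief subliminal stimulus is
followed, after a finely varied delay, by a two-image temporal-integration
task held at its ~50% accuracy threshold. If the subliminal stimulus resets
an ongoing neuronal rhythm, task accuracy should wax and wane as a function
of the delay, turning accuracy-by-delay into a short time series whose
spectrum carries the signature of the underlying rhythm. The canonical
design is 19 subjects x 2 sessions, delays sampled every video frame
(1/60 s, ~16.6 ms) over roughly 312-617 ms before the task stimuli, and 20
threshold trials per delay per session.

`behavosc` implements the full chain — trial aggregation, detrending,
zero-padded single-taper spectra, three surrogate-data nulls, and a
cluster-based permutation test — together with a synthetic-experiment
generator (logistic observers, the two adaptive calibration staircases,
controllable oscillatory accuracy modulation) so that every stage can be
exercised, calibrated and stress-tested without any raw data.

## Pipeline

1. **Aggregation** (`aggregate_accuracy`): fraction correct among
   threshold-SOA trials per delay, per subject and session. Control-SOA and
   catch trials are excluded.
2. **Detrending** (`detrend_series`): ordinary least-squares polynomial
   residuals in delay; order 1 (linear detrend + demean) is the default,
   order 2 the control analysis. The abscissa is centred and scaled to
   [-1, 1] for conditioning; because the projection spans the same column
   space as raw-millisecond polynomials, residuals are identical either way
   (property-tested).
3. **Spectrum** (`compute_power_spectrum`): the 19-sample series is
   multiplied by a single dpss (Slepian) taper with 3 Hz half-bandwidth
   smoothing (time-half-bandwidth 19/60 x 3 = 0.95), zero-padded to 1 s
   (60 samples), Fourier-transformed, and the squared magnitude is kept on
   the integer grid 1-29 Hz — everything between DC and the 30 Hz Nyquist
   frequency of the one-frame sampling. The taper is applied *before*
   padding: smoothing is a property of the data window, not of the padding
   zeros. Power is plain `|X|^2` with a unit-RMS taper; absolute units
   cancel because observed and surrogate spectra share every setting.
4. **Surrogates** (`surrogate_time_shuffle`, `surrogate_random_accuracy`,
   `fit_ar1` + `surrogate_ar`): see below. Each produces, per subject,
   a reduced spectrum (`reduce_surrogates`): a per-frequency statistic over
   repetitions within session (median by convention), then the mean across
   the subject's sessions — mirroring the sessions-then-subjects averaging
   of the observed spectra.
5. **Inference** (`cluster_permutation_test`): per-frequency paired t
   statistics on observed minus surrogate power across subjects
   (df = n - 1 = 18, cluster-forming threshold `t_critical(18, 0.05)` =
   1.734), maximal contiguous suprathreshold runs summed into cluster
   statistics, and a largest-cluster permutation null from random
   per-subject condition swaps (sign flips of the paired differences),
   10,000 by default, with the `(1 + k)/(1 + B)` p-value convention.

## The three surrogate nulls

* **Time shuffle** permutes the *raw* accuracy values across delays and
  re-runs detrend + FFT per repetition: the value multiset survives,
  temporal order does not.
* **Random accuracy** redraws each delay's accuracy as the mean of `n`
  fair Bernoulli trials (the observed trial count) plus an offset equal to
  the session mean minus 0.5, so surrogate data carry exactly the binomial
  counting noise of the design at the observer's performance level. The
  alternative `bernoulli = "mean"` parameterisation draws
  Bernoulli(session mean) directly; the two differ only in variance
  (p(1-p) vs 0.25) and are both exposed.
* **AR model** fits `X_t = c + phi X_{t-1} + eps_t` to the detrended series
  (Gaussian ML via `stats::arima`, conditional-least-squares fallback) and
  simulates matched-length realisations with Gaussian innovations of the
  fitted residual SD (100-sample burn-in): the null retains lag-one
  autocorrelation, which pure shuffles destroy.

All three run through literally the same detrend/taper/pad/FFT code path as
the observed data (one internal function; asserted by a construction test).

## Calibration: what the tests actually show

Two properties of this inference chain deserve emphasis; both are computed
by the test suite and the acceptance script rather than asserted.

**The median reduction biases the comparison.** Spectral power is strongly
right-skewed on 19-sample windows, so the median over surrogate repetitions
sits well below the mean. The observed per-subject value is a single draw
(mean of 2 sessions) whose expectation *is* the mean. Under a pure null
(no oscillation, independent binomial trials) the paired differences are
therefore positive on average at every frequency — about +2 in t units at
this design size — and the sign-flip permutation null, which assumes
symmetric differences, does not absorb the shift. Measured across 200 null
experiments (500 repetitions, 1000 permutations), the fraction showing at
least one cluster at p < 0.05 is ~0.93-1.00 for all three methods. With
`surrogate_reduce = "mean"` the time-shuffle and random-accuracy pipelines
calibrate to ~0.02. The median remains the package default because it is
the field's convention for this analysis; for null-calibrated inference use
the mean reduction, and read positive clusters under the median reduction
with this bias in mind.

**AR surrogates are additionally biased on very short series.** The ML
innovation variance on 19 points is biased low (no small-sample degrees-of-
freedom correction), so AR surrogate power sits systematically below
observed power even under the mean reduction (~0.8 false-positive rate in
the same benchmark). AR nulls are the right response to autocorrelation
critiques, but at this window length their variance calibration, not just
their spectral shape, matters.

A related geometric fact: the order-1 detrend is itself a filter. It
suppresses expected power in bins 1-4 Hz (to ~0.17/0.39/0.72/0.98 of the
flat level, matching the closed form `E[P(f)] = sigma^2 ||f_f' W Q||^2`),
identically for observed and surrogate spectra. "Flat" white-noise spectra
are flat only above that ~5 Hz passband edge, and clusters below
`min_full_cycle_frequency(0.288) =` 3.47 Hz rest on partial cycles.

## The synthetic experiment

`generate_experiment` emulates the study conditions: 19 subjects, 2
sessions, 19 delays (whole frames 19-37; the 19 x 20 = 380 threshold trials
per session fix the grid size, since an 18-point grid ending exactly at
600 ms cannot reproduce that count), 20 threshold trials per delay, four
control SOA conditions (0 ms; threshold +/- one frame; threshold + 48 ms —
the long condition is realised above threshold only, since a "short"
condition at 0 ms already exists), 10% catch trials split evenly real/fake.
Threshold-trial accuracy is
`clamp(base + b1 t + b2 t^2 + sum a_i cos(2 pi f_i t + phi_i), 0, 1)`,
drawn independently per trial; clamping events are counted and reported.
Control trials follow the observer's SOA psychometric function; catch
responses follow the detection function with a configurable false-alarm
rate (default 0.1, a value the design leaves free). Identical seeds yield
byte-identical tables.

Observers are logistic with independent detection and integration
functions. Defaults: detection slope 80 per Weber-contrast unit (one grey
step of 0.01 on the 0.38 background, 2.6% contrast, moves detection ~2
logits), integration anchored at exactly 50% at the observer's threshold
SOA, lapse 0.02, guess 1/16 (16 candidate grid locations). The default
observers are homogeneous across subjects; real panels vary, so
between-subject variance in the synthetic null is, if anything, optimistic
for the t-test's denominator.

Both calibration staircases are implemented with their printed rules. The
contrast staircase decrements the grey value on each "yes", increments once
after 10 consecutive "no", and stops at 20 consecutive "no" — the streak
counter is *not* reset by the increment at 10, the only reading under which
the stop rule is reachable. Non-evaluated shams at random grey values are
interleaved (probability 0.2 here; the design does not pin it down). The
SOA staircase is 2-up/2-down in one-frame steps from 26 ms, with
termination when the variance of the last 20 evaluated SOAs drops below
0.5 ms^2. Taken literally in milliseconds that requires 20 consecutive
evaluated trials at one level, which stochastic observers essentially never
produce — the rule only plausibly fires for observers far more consistent
than Bernoulli draws, or with the variance read in step units. The package
keeps the literal millisecond reading (the threshold is a parameter), and
the tests verify what the rule actually implies: deterministic observers
cycle between two adjacent levels forever, and the visited levels
concentrate around the 50% point, which is what the 2-up/2-down rule
targets.

The contrast bookkeeping is deliberately double: `weber_contrast`
((L-Lb)/Lb) makes a 0.01 grey step 2.6% on the 0.38 background, while
`midpoint_contrast` (2(L-Lb)/(L+Lb)) maps grey 0.47 to 21.2% and 0.57 to
40%; the source arithmetic mixes the two conventions, so both are provided
and neither is asserted as "the" contrast.

## Numerical and design choices

* Frame duration is exactly 1/60 s everywhere; 16.6 ms is a display
  rounding.
* The dpss taper is computed from the classical symmetric tridiagonal
  eigenproblem; the "3 Hz smoothing" is read as the half-bandwidth of a
  single Slepian taper (the taper family is not pinned down by the source
  analysis; Hann and no-taper are available).
* `pad_seconds` must cover the series; frequency-grid spacing is
  `1/pad_seconds`.
* Permutation p-values use the +1 correction, so `p >= 1/(B+1)` and ties
  count against significance.
* Two-sided cluster formation (threshold ±1.734, separate positive and
  negative largest-cluster nulls) is the default for exploratory use;
  `tail = "one_sided_positive"` reproduces the convention of reporting
  positive clusters only and is what the calibration benchmarks use.
* All randomness flows from one master seed through `derive_seed(seed,
  label)` (FNV-1a label hashing), so generation, each surrogate method per
  subject/session, and the permutation draw are independently reproducible.

## Problem sizes used in the shipped tests

The test suite and `scripts/acceptance.R` run the full design (19 x 2 x 20)
with 500 surrogate repetitions and 1000 permutations per experiment; the
type-I benchmark uses 200 null experiments (100 per variant in the script)
and the 11 Hz recovery benchmark 100 experiments with amplitude 0.12 on
base 0.55 — recovered in ~100% of runs. Monte-Carlo checks of observers and
staircases use 10^4-10^5 draws or 500 staircase runs. These sizes give
binomial standard errors comfortably inside the asserted bounds while
keeping a complete run in minutes on one core.

## What passing tests do and do not show

The generator draws trials independently across delays and trials given the
delay-dependent probability; real behaviour has serial dependencies
(learning, fatigue, streaks), session non-stationarities and heterogeneous
observers. Passing calibration on this synthetic null therefore shows the
machinery is correct and internally consistent, not that any particular
empirical cluster is rhythmic; conversely, the measured anti-conservativeness
of the median-reduction comparison is structural — it does not depend on
those idealisations and will not improve on real data.
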