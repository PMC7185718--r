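---
title: "Modeling bistable auditory streaming across a perceptual hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bistable auditory streaming across a perceptual hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A repeating A-B-A triplet of pure tones is the classic bistable stimulus of
auditory scene analysis: listeners hear it either as one galloping stream
(*fused*) or as two interleaved isochronous streams (*segregated*), and at
intermediate A-B separations perception alternates spontaneously between
the two. `bistream` simulates this phenomenon end to end: it synthesizes
the acoustic stimulus, passes it through a three-stage model of the
auditory system, injects competition dynamics (adaptation, mutual
inhibition, noise) at any of the stages, converts the model's scene
interpretation into a continuous fused/segregated report, and scores that
report with the statistics used to compare such models against human
continuous-report data.

The scientific question the machinery serves: *where* in the processing
hierarchy can adaptation, inhibition and noise plausibly generate
perceptual bistability? The package lets the magnitudes of those three
ingredients be placed at a peripheral (tonotopic) stage, a central
(spectral-scale) stage, an object (scene-interpretation) stage, or any
combination, and sweeps them over ensembles of model variants.

# The three analysis stages

**Peripheral** (`peripheral_analysis()`). The 8 kHz waveform passes
through a bank of causal fourth-order gammatone-like constant-Q filters on
a log-frequency axis (default 96 channels, 24 per octave from 220 Hz,
Q = 8; the top channel stays below the 4 kHz Nyquist frequency). Lateral
inhibition subtracts each channel's lower neighbor, the result is
half-wave rectified, low-passed at 10 Hz (first-order IIR, computed
exactly at the decimated 20 ms frame rate), and scaled by a fixed
calibration gain of 10 so the tonotopic ridge of a standard-level stimulus
peaks near 1 — the interior of the stage's soft bounds (0.005, 5). The
competition transform is then applied across frequency channels.

**Central** (`central_analysis()`). Each spectrogram frame is convolved
along log-frequency with analytic (Hilbert-completed) wavelets tuned to
0.5, 1, 2 and 4 cycles/octave. The seed shape is the negated second
derivative of a Gaussian; because that shape's spectral peak falls at
~0.225 of its nominal scale, the kernel width is rescaled so the passband
peaks exactly at the named scale (a 1 cycle/octave ripple is maximal in
the 1 c/o channel). Sampled kernels are forced to zero mean so a flat
spectrum produces no response. Competition acts on the per-scale mean
magnitudes and each scale slice is rescaled by the ratio of competed to
raw magnitude, leaving phases untouched.

**Object** (`object_analysis()`). Two grouping principles are composed:

* *Temporal coherence* — the central representation is filtered along time
  with analytic modulation kernels at 2, 4, 8 and 16 Hz (32 Hz would
  exceed the 25 Hz Nyquist frequency of the 20 ms frame rate and is
  excluded from the defaults), and each trailing 0.5 s window, advanced at
  the 100 ms object step, is factorized as a rank-2 non-negative matrix
  (rows: window frames × rates, columns: frequency × scale) by
  multiplicative updates from a deterministic NNDSVD start. The two
  components recover the A-like and B-like spectra when the stimulus
  separates them.
* *Object continuity* — components are assigned to up to two sources by a
  greedy sequential Bayesian procedure. Each source is a multivariate
  Normal over the whitened component features with conjugate
  Normal-Inverse-Gamma priors on its mean and shared variance, plus a
  Beta-Bernoulli presence model. Six interpretations are tracked, one per
  pair of prior hyper-parameters: mean pseudo-count kappa in {15, 20}
  frames and per-coordinate variance scale beta in {0.25, 0.5, 0.8}. A
  narrow variance prior expects slowly moving sources and favors
  splitting the stationary tones into two streams; a broad prior tolerates
  the movement of a single fused source.

Per frame, each interpretation's best assignment score (the joint log
predictive of the components under the assignment, by the chain rule, with
the presence terms) is min-shifted across interpretations and scaled so
the running maximum after the first second equals 1. Competition across
the six interpretation units then selects the dominant interpretation, and
its sources' Wiener-style masks (squared component shares over the whole
scene) are inverted back to time-frequency by matched-filter
back-projection, clipped so the sources partition the full reconstruction.

# The competition transform

The same transform `F[x(t)]` applies at every stage to a vector of unit
weights (`competition_run()`): the input is softly bounded into the
stage's range, multiplied by `(1 - c_a a(t))` (adaptation, a low-passed
trace of the output, time constant 3 s) and `exp(n(t))` (slow Gaussian
noise, an Ornstein-Uhlenbeck process with magnitude 0.2 and time constant
0.5 s), reduced by `c_b b(t)` (inhibition, a low-passed trace of the mean
distance-weighted output of the other units, time constant 0.35 s,
neighborhood strength 6), and half-wave rectified.

Two placement choices matter and are deliberate:

* The third-order 1.5 Hz smoother drives the *adaptation and inhibition
  traces*, not the feed-forward output: its role is to keep the brief
  silences between tones from resetting the slow dynamics. Smoothing the
  feed-forward signal instead would erase the 2-16 Hz modulation content
  that the temporal-coherence analysis depends on.
* The inhibition trace integrates the *mean* pooled drive
  `B x y / n_units`. With a summed drive, a stage with 96 channels and a
  large `c_b` locks into permanent winner-take-all at every calibration,
  because the pooled inhibition exceeds the bounded drive by an order of
  magnitude; the mean form lets the same `c_b` grid span comparable
  regimes at stages with 96, 4 and 6 units.

The soft bound is a softplus-clip with sharpness 2000 on the normalized
range: an identity over virtually the whole interval with smooth
saturation at both edges. (A softer clip leaves a pedestal on silent
channels that propagates into spurious edge structure downstream.)

# Numerical and design choices

* **Whitening nugget (0.003).** The continuity correlation
  `exp(-(log f_i - log f_j)^2 / sigma_f^2)` with `sigma_f = 5` log-Hz is
  singular (columns sharing a frequency are perfectly correlated), so a
  diagonal nugget is added before the Cholesky factorization. Its value is
  fixed so the typical per-coordinate energy of whitened component
  observations (~0.3-0.5) falls inside the span of the beta grid — i.e.
  so the variance-scale prior actually brackets the observation scale.
* **Per-coordinate variance priors.** `alpha` and `beta` are treated as
  per-coordinate hyper-parameters and scaled into the joint
  `d`-dimensional prior as `alpha d/2`, `beta d/2`. Passing them into the
  joint prior verbatim gives a 2-degree-of-freedom t prior whose tails
  make creating a second source impossibly expensive in a 384-dimensional
  feature space.
* **kappa in frames.** The mean pseudo-counts are 15 and 20 frames —
  commensurate with the 30-frame source history, so posterior means track
  their sources. (With pseudo-counts of hundreds of frames the mean never
  moves and component separation becomes invisible to the likelihood.)
* **Deterministic factorization.** The NMF is initialized from the
  window's leading singular pairs, never from random draws, so all
  stochasticity in a simulation comes from the competition noise and a
  model with zero noise is exactly reproducible run to run.
* **Read-out thresholds.** A channel counts as active over a 0.5 s window
  when its 95th within-window quantile exceeds `theta_b = 0.3` of the
  representation's own global 99.6th quantile (a robust peak estimate);
  mask and reference are each thresholded against their own distribution
  because their amplitude scales differ. The dominant mask's active
  bandwidth relative to the input's decides the label: a narrow mask (one
  stream of two) is read as segregated below the 0.75 ratio threshold
  (`direction = "coherent"`; the `"literal"` direction implements the
  opposite convention). Labels are merged, and reversions shorter than
  250 ms are discarded.

# Evaluation machinery

`proportion_segregated()`, `response_deviation()` (per-run RMS difference
from the reference mean proportions over the 3/6/12 st conditions,
averaged over runs), `length_deviation()` (two-sample Kolmogorov-Smirnov
statistic on pooled per-individual z-scored log percept lengths) and
`deviation_ratio()` (each model deviation scaled by the mean deviation of
individual reference listeners, then averaged; 1 = listener-typical)
implement the scoring. `buildup_curve()`, `bootstrap_ci()` (percentile,
10,000 resamples) and `log_density()` (Gaussian kernel on log durations,
Silverman bandwidth, Jacobian-corrected) cover the descriptive statistics.

`generate_reference()` provides a synthetic listener population with the
statistical structure the metrics assume — logit-normal per-condition
segregation proportions around configurable means (defaults 0.15 / 0.5 /
0.85, which are *not* measured values) and listener-specific log-normal
percept durations — so the whole pipeline is testable without any
external data. What passing tests against this population shows is that
the machinery is wired correctly, not that the model reproduces any
particular cohort.

`ensemble_grid()` / `enumerate_models()` / `run_ensemble()` /
`aggregate_ensemble()` implement the within-stage sweep (10 levels of
adaptation × 10 of inhibition × 3 stages = 300 models) and the
across-stage sweep (5 levels on all six magnitude axes = 5^6 = 15,625
models; each marginal (stage, c_a, c_b) cell aggregates the minimum ratio
over its 5^4 = 625 models), with the early-termination rule (after the
first ten 6 st simulations of an across-stage model, stop if the
provisional deviation ratio exceeds 1) and deterministic per-simulation
seed derivation. The full across-stage sweep is a cluster-scale job; the
command-line front-end (`inst/cli/bistream.R`) supports sharding.

# Problem sizes used in the packaged checks

The test-suite and acceptance-script simulations use the full 48 s,
100-repetition stimulus for the hallmark checks (five seeds per condition,
with the deterministic peripheral/central/grouping phases shared across
seeds via `run_condition()`), and shorter 5-25 s stimuli with a reduced
48-channel filterbank for unit-level integration checks. Ensemble code
paths are exercised on 2-level grids with single simulations per model.

# Known limitations

* For models whose competition lives only in the object stage, the
  interpretation likelihood gaps in the high-dimensional feature space are
  large relative to the noise magnitude, so dominance alternates among
  neighboring-prior interpretations and percept alternation is expressed
  through the bandwidth read-out; run-to-run percept variability of such
  models is therefore much smaller than for peripheral- or central-stage
  models, and their pooled z-scored percept lengths cluster rather than
  forming the broad log-normal spread of human reports.
* The read-out quantizes percept boundaries at the 250 ms analysis step.
* Loudness calibration, middle-ear pre-emphasis, additional feature
  dimensions (pitch, location) and more than two concurrent sources are
  out of scope.
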