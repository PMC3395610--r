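---
title: "Envelope coding of electric-organ-discharge scenes: models and methods"
author: "eodcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope coding of EOD scenes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eodcoding)
```

This vignette is the package's account of the science it implements:
the composite-signal model, the two-level envelope analysis, the P-unit
electroreceptor model, the coding metrics, and — importantly — the
numerical and design choices made where the underlying physiology or
the published phenomenology leaves the implementation open.

## The composite signal and its envelopes

A wave-type electric fish emits a quasi-sinusoidal electric organ
discharge (EOD) at an individual frequency `f` (700–1100 Hz in the
species this pipeline emulates). Near a "receiving" fish, the fields of
`N` fish superpose. Approximating each EOD by its fundamental, the
received signal is

$$S(t) = \sum_{n=1}^{N} A_n\,(1 + \sigma_n \xi_n(t))\,
         \sin(2\pi f_n t + \phi_n),$$

with the receiving fish fixed at `A₁ = 1, σ₁ = 0`. A moving neighbour's
effective amplitude varies with distance and orientation; the model
captures this with a scaled Ornstein–Uhlenbeck process (OUP) `ξₙ(t)` —
zero-mean, unit-variance, exponentially correlated Gaussian noise whose
spectral power is concentrated at the low frequencies characteristic of
swimming. Phases are set to zero: the envelope spectra analysed here do
not depend on them (phase matters for other computations, such as
jamming avoidance, which are out of scope).

Two envelope orders carry distinct information:

* **E1**, the amplitude modulation of `S`, beats at the pairwise EODf
  differences `|f₁ − fₙ|` — the neighbours' identities;
* **E2**, the envelope of E1, varies with the motion-driven amplitudes
  and, for three or more fish, at the *secondary beats* (differences
  between beat frequencies).

For two fish with `A₂ ≪ 1`, a first-order expansion of the envelope
gives the amplitude modulation `1 + A₂(1 + σ₂ξ(t))\cos(2π Δf t)`: a
combined sinusoidal + random AM whose instantaneous contrast (half
peak-to-trough difference over the mean, collected per beat half-cycle)
has mean `≈ A₂` and SD `≈ A₂σ₂`. This is `predict_am()`, and it is what
makes contrast statistics measured from tank recordings interpretable
as model parameters: `A₂` tracks the inverse of inter-fish distance,
`σ₂` the vigour of swimming.

### Generator defaults = study conditions

The generator's defaults are the conditions of the emulated tank
recordings, not tunables: EODfs 827/763 Hz for the representative pair
(beat 64 Hz) and 831/740/889 Hz for the triplet (beats 91 and 58 Hz,
secondary beat 33 Hz); mean contrast in 0.07–0.20 with contrast SD/mean
0.5–0.9; recordings at 100 kHz with a 20 kHz fast mode for
envelope-only analyses (envelopes live below 200 Hz, so any rate
comfortably above twice the EODf is equivalent; the fast mode was
validated against 100 kHz runs).

Two published numbers needed interpretation:

* The representative pair is printed as the pair (0.143, 0.08). Because
  the population-level fluctuation scale is stated as 0.5–0.9, the
  package reads the pair as (mean contrast, SD of contrast), i.e.
  `A₂ = 0.143`, `σ₂ = 0.08/0.143 ≈ 0.56`. The alternative reading
  (`σ₂ = 0.08` directly) is available via
  `two_fish_scene(convention = "amplitude")`. The same convention
  governs the parameter sweeps: the "fixed σ = 0.1" of the amplitude
  sweeps must be the SD of contrast (0.1 would be far outside the
  0.5–0.9 range of the relative scale, and at the sweeps' fixed
  `A₂ = 0.2` it corresponds to relative 0.5, inside it). Consequently
  `run_parameter_sweep()` sweeps `A₂` at **fixed absolute contrast SD**,
  letting the relative scale fall as `SD/A₂`. This is not a cosmetic
  choice: in the pure model, every beat-crossing statistic scales with
  `A₂`, so at fixed *relative* scale the period CV is exactly flat in
  `A₂` (verified with paired seeds to 1e-5) and the beat-peak width
  grows with `A₂`; at fixed *absolute* SD the width barely changes and
  the CV falls as the relative fluctuation shrinks — which is the
  phenomenology the sweeps are expected to reproduce.
* The OUP correlation time fitted to tank data is not legible in the
  available text; the package default `τ_c = 0.5 s` is a configuration
  choice consistent with the seconds-scale decay of measured E2
  autocorrelations, and it is exposed in `eod_source()`.

The OUP is discretized with the exact AR(1) update
`ξ_{k+1} = αξ_k + √(1−α²)·w_k`, `α = e^{−Δt/τ_c}`, initialized from the
stationary distribution, so unit variance holds at any step size (an
Euler–Maruyama scheme would be biased at coarse steps). Instantaneous
amplitudes are deliberately **not clipped** at zero — large `σₙ` can
drive `1 + σξ` negative, the model has no clipping, and the envelope
analysis treats magnitudes. Per-fish noise streams are derived from the
master seed by fixed offsets (`child_seed()`), so adding a fish never
perturbs the others' realizations.

What the generator does *not* emulate: EOD harmonics (real EODs are
only quasi-sinusoidal), chirps (transient frequency excursions used in
communication), the spatial geometry of the dipole fields (amplitude
fluctuation is a lumped stand-in for distance, bending and turning),
and self-motion of the receiving fish. Tests passing on synthetic
scenes therefore demonstrate the pipeline's correctness under the
model's assumptions, not the model's completeness with respect to real
recordings.

## Envelope extraction

E1 is the magnitude of the analytic signal (FFT-based Hilbert
transform), low-pass filtered to remove the remnant spectral peak at
the EODf. The cutoff is 200 Hz — above every beat of interest, below
the EODfs. The filter is a 4th-order Butterworth applied forward and
backward (zero phase): envelope timing must be preserved because the
envelopes are later cross-correlated with spike trains.

E2 is extracted per 0.1 s window of E1: the window mean is removed, the
analytic-signal magnitude of the residual beat oscillation is taken,
the mean is added back, and the windows are concatenated; a 50 Hz
zero-phase low-pass then suppresses the segment-boundary
discontinuities that concatenation leaves open. The windowed procedure
is validated against the independent peak-connection envelope
(`extract_envelope_direct()`, monotone piecewise-cubic interpolation
through local maxima — monotone interpolation avoids the overshoot a
plain cubic spline would add), with the two agreeing within 5%
normalized RMS on all fixtures.

Numerical conventions, chosen once and used throughout: local extrema
are strict (`x[i]` greater than both neighbours), plateaus resolve to
their left-most sample; the first and last 50 ms of any envelope are
treated as filter-settling edges and excluded from statistics; the E2
window must exceed one beat period (checked from interior
mean-crossings, which is robust to filter-edge transients).

### Period statistics: crossings of the local mean

Successive E1 periods are measured between upward crossings with
sub-sample linear interpolation, histogrammed on 0.02 ms bins; the mode
is the center of the maximal bin (ties take the lower bin) and the CV
is SD/mean. The crossing reference is the **local** mean of E1 (its
zero-phase low-pass at 20 Hz, below any beat) rather than the global
record mean. The record mean of a beat envelope sits a quadratic-order
offset (`≈ A₂²/4`) above the oscillation center; crossings against it
systematically miss beats whenever the fluctuating beat amplitude dips
below that offset, and because the offset grows with `A₂` this
inverts the true dependence of period jitter on neighbour amplitude.
Detrending removes the artifact: the noiseless beat then gives CV at
the numerical floor, jitter grows with `σ₂`, and locking improves with
`A₂`. The near-DC trend filter rings over several of its own time
constants, so an extra `2/cutoff + 0.15 s` settling margin is dropped
at each end before crossings are counted.

## Spectral estimation

All spectra are Welch averaged modified periodograms: Hann windows,
per-segment mean removal, 50% overlap, one-sided density normalization
(the integral over frequency equals the signal variance; the tests
assert this Parseval identity within 5% on every fixture class).
Defaults are 2 s segments — for the standard 12 s records this gives 11
averages and 0.5 Hz bins, enough to separate the 58/64/91 Hz beats and
resolve the 33 Hz secondary beat. Per-segment demeaning implies a
caveat the test fixtures respect: segments must be long against the
signal's correlation time, or genuine low-frequency variance is
discarded with the mean.

Peak quality is quantified as in the underlying experiments: height of
the local maximum near the expected frequency, width between the two
flanking crossings of a reference level (linearly interpolated), and
resolution = height/width. The reference level is a parameter: widths
are only comparable across conditions when read at one common absolute
level, so `run_parameter_sweep()` anchors it at ten times the spectral
floor of the first sweep condition. Reading the width near the floor —
not at half maximum — makes it sensitive to the motion-driven
broadening at the peak's base, which is the effect of interest.

The autocorrelation is mean-removed, variance-normalized and averaged
over 15 s segments (FFT-based, so long lags on dense grids stay cheap).
The OUP correlation time is recovered by least squares of
`a·exp(−Δt/τ)` over lags with correlation above 0.05, with the
amplitude `a` profiled out analytically. Leaving `a` free matters:
envelope-estimation noise adds an uncorrelated component that inflates
the lag-0 variance and rescales the normalized autocorrelation without
changing its decay, so pinning `a = 1` biases `τ` low, and fitting in
log space instead lets tail noise dominate. On 120 s two-fish scenes
the profiled linear-space fit recovers `τ_c = 0.5 s` with a seed-mean
within a few percent.

## The P-unit model

P-unit electroreceptor afferents are simulated with the leaky
integrate-and-fire model with dynamic threshold (LIFDT):

$$\tau_v \frac{dv}{dt} = -v + g\,H(s(t))\,s(t) + \tau_v\sqrt{2D}\,\xi(t),
\qquad
\tau_\theta \frac{d\theta}{dt} = \theta_0 - \theta,$$

with a spike when `v ≥ θ`, then `v → 0` and `θ → θ + Δθ`. The Heaviside
gate `H` half-wave rectifies the stimulus, as transduction at these
receptors does; the intrinsic noise is integrated as `√(2D·dt)·N(0,1)`
per Euler step; the step is 0.01 ms (the integration loop is compiled
C++, using R's RNG so a seed fully determines a run).

The defining statistic of a P-unit is its **P-value**: baseline firing
rate (EOD carrier alone) divided by the EODf — the probability of
firing on any given EOD cycle. Empirically P-values are log-normal
with mean 0.26 over 0.1–0.6.

The parameter values of the source model are not legible in the
available text, so the package adopts defaults in the published LIFDT
P-unit range — `τ_v = 1 ms`, `τ_θ = 10 ms`, `Δθ = 0.05`, `θ₀ = 1`,
`g = 2.2` — **and never relies on them to place a unit**: the
heterogeneity knob is always calibrated against a measured P-value.
These defaults are repository choices; with them, baseline firing is
subthreshold at `D = 0`, the realized P-value rises monotonically with
`D` through the full empirical range, and phase locking to the EOD
cycle is strong (vector strength ≈ 0.85 at P = 0.26).

### Two calibration axes, and why both exist

`calibrate_noise_for_pvalue()` bisects the noise intensity `D` (in log
space, since P varies smoothly there) against a 20 s baseline
simulation with a fixed calibration seed, so the P(D) map is a
deterministic monotone function and the bracket's monotonicity can be
verified before bisecting. Calibration seeds are separate from analysis
seeds; calibration never consumes analysis randomness.
`sample_population()` draws targets from the truncated log-normal
(shape 0.4, chosen so the truncated mean stays at 0.26), tabulates the
shared P(D) map once on a 25-point log grid, and inverts it per unit
with a few refinement steps — this is what makes 200-unit populations
cheap.

`calibrate_threshold_for_pvalue()` instead bisects the resting
threshold `θ₀` at fixed small noise (`D = 0.01`), so units differ in
*excitability* rather than *noisiness*. The distinction is not
cosmetic. Noise-tuned heterogeneity reproduces the population's firing
statistics, the beat coherence, and the low-P advantage for
motion-band (E2) information. But in the narrowband-RAM control
(70–120 Hz random AM, the laboratory stand-in for a group of static
conspecifics), noise-tuning makes carrier-band coherence *fall* with
P — raising `D` adds noise faster than the extra spikes help, across
every gain, threshold increment and RAM contrast we probed. The
published control shows carrier-band coherence *rising* with P while
envelope coherence falls, and that is exactly what excitability-tuned
units do: a more excitable (higher-P) unit fires often enough to track
the fast modulation linearly, while a threshold-dominated (low-P) unit
fires only near envelope peaks, effectively demodulating the stimulus.
The symbol of the parameter varied in the source work is not legible in
the available text; the package therefore exposes both axes, uses
noise-tuning for population statistics (where "each unit with its own
internal noise" is explicit) and excitability-tuning for the RAM
control, and documents the choice here.

Spike trains are represented by their times on the 0.01 ms grid and
binned to 0.5 ms (Nyquist 1 kHz, above the EODf band) for spectral and
coherence analysis. Population rates use 0.1 s windows — longer than
any beat cycle, so the windowed rate follows E2.

## Coding metrics

Coherence is estimated from the same Welch machinery as the spectra
(`|S_xy|²/(S_xx S_yy)` per frequency). Its estimate is biased upward by
about `1/n_segments`, so at least 8 segments are required and the
standard records for coherence work are 15–60 s; the 0.15 reference
level used for coherence-peak widths sits above this floor at those
lengths. Coherence against stochastic spike trains uses single long
records, as the underlying single-unit analyses do; averaging over
seeds happens only at the statistics level (sweeps, acceptance checks).

The mutual-information rate uses the Gaussian-channel lower bound
`−∫ log₂(1 − C(f)) df` on the native grid (trapezoidal), excluding the
DC bin (a mean-rate offset carries no envelope information) and capping
`C` at `1 − 10⁻⁶` before the logarithm. The motion band is 0–20 Hz,
where swimming concentrates its power.

## Problem sizes and reproducibility

The package's own test and acceptance runs use desk-scale versions of
the tank-scale analyses: 12 s records for spectra (as in the source
analyses), 60 s × 20 seeds for contrast statistics, 120 s scenes for
period histograms and correlation-time recovery, 15–30 s records for
coherence and MI, parameter sweeps of 5 grid values × 5 seed
replicates (the tank-scale figure sweeps average 50 OUP realizations),
and trend claims asserted as the sign of the Spearman correlation
across the grid — sweeps reproduce orderings, not figure-only absolute
values. Sweeps use common random numbers: each replicate reuses one
noise realization across every parameter value (as the tank-scale
sweeps reuse their OU realizations across settings), so value-to-value
differences reflect the parameter rather than the draw — without this
pairing, the weaker trends would need on the order of the tank-scale 50
replicates to resolve. Every stochastic stage takes its seed from a
named `child_seed()` stream of one master seed; rerunning any
configuration reproduces its outputs bit-identically.

## Known limitations

* The composite-signal model is phenomenological: amplitude
  fluctuation stands in for all spatial effects. No field geometry, no
  electric-image structure, no self-motion.
* Absolute spectral levels depend on the energy rescaling used when
  comparing simulation to recordings; the package implements
  rescaling-to-equal-total-energy as an option but leaves the absolute
  factor free, and no analysis here depends on absolute levels.
* The LIFDT parameter defaults are repository choices within published
  ranges, made robust by P-value calibration; conclusions that depend
  on fine ISI structure beyond phase locking and rate should be drawn
  with care.
* Coherence-based MI is a lower bound valid for Gaussian stimuli;
  nonlinear encoding (e.g. the envelope demodulation by low-P units)
  carries information this bound does not credit.
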