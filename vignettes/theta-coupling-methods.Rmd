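---
title: "Methods: linking LFP theta to multineuronal membrane potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking LFP theta to multineuronal membrane potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thetalink` analyses simultaneous extracellular (LFP) and intracellular
(Vm) recordings from hippocampal CA1 at a 500-Hz analysis rate, asking how
the theta rhythm (3–10 Hz) in single-cell membrane potentials relates to
the theta rhythm of the field. This vignette documents the model
assumptions, the tunable parameters, the numerical choices, and the
limitations of the validation strategy.

## Theta-period detection

A complex Morlet wavelet transform (centre parameter ω₀ = 6) is evaluated
on a frequency grid covering 1–100 Hz (0.25-Hz steps up to 20 Hz where
theta lives, 1-Hz steps above). Coefficient magnitudes are
amplitude-normalized: a unit sinusoid produces a unit ridge regardless of
frequency, so band means compare fairly across frequencies.

A sample belongs to the theta state when the mean magnitude over 3–10 Hz
exceeds `mean + k·SD` of a baseline statistic. The baseline is read as the
*time series of mean magnitude across the whole 1–100 Hz grid*, with its
mean and SD taken over the (edge-trimmed) recording; only the upper bound
is meaningful. An alternative reading — per-frequency baselines pooled
afterwards — exists; the threshold-scan calibration makes the pipeline
robust to this choice, because `k` is selected where detected-period
overlap across simultaneous channels is most distinguishable from
surrogate overlap (two-sample KS *D* maximized over k ∈ {1, 2, 3, 4}).

Morphological cleanup deletes theta runs shorter than 1 s first and then
fills shorter-than-1-s gaps, in that order; the order matters and this one
is idempotent under re-application. Intervals are half-open
`[start, end)` seconds, which makes overlap (Dice) arithmetic exact.

Because the threshold is a multiple of the recording's own baseline SD,
detection is invariant under global amplitude rescaling — LFP amplitudes
can therefore be treated as relative, and all power statistics are
Z-scored (per 1-s or 0.1-s bins, maximum across the band per bin,
population-SD normalization across bins).

**Edge bias.** The Morlet support at theta frequencies is 0.1–0.3 s
(σ_t = ω₀/2πf), so the band-power ramp at a theta onset is smeared over a
few hundred milliseconds. The 2-SD threshold crosses that ramp at a height
that depends on the recording's overall duty cycle, which shifts *all*
detected edges of a recording coherently — in noiseless synthetic data by
up to ~0.3 s while interval overlap (Dice) with the true epochs stays
above 0.95. Edge positions should therefore be read with a ±0.5 s (one
wavelet support) resolution; detection *membership* is much more accurate
than edge placement.

**Spiking cells.** Action potentials are broadband and tens of times
larger than subthreshold theta, so they inflate the 1–100 Hz baseline and
can suppress theta detection on Vm channels entirely. `despike_trace()`
replaces ±4 ms around each threshold crossing with a linear bridge; it is
off by default (the 3–10 Hz bandpass attenuates 2-ms transients enough for
filtering-based analyses) but recommended before *wavelet* analysis of
spiking cells, and used by the acceptance script.

## Coupling statistics

- Power coupling: Pearson *r* between per-bin theta powers of two
  channels, with `t = r·sqrt((n−2)/(1−r²))` and a two-sided p. Bins of 1 s
  (segment analyses) or 0.1 s (fast tracking).
- Dice overlap `2|A∩B|/(|A|+|B|)` is computed on interval measure; two
  empty sets give 0 (not 1), so silent channels never look perfectly
  synchronized.
- Surrogates shuffle the timings of the individual periods while keeping
  each duration: durations are permuted and inter-period gaps drawn as
  scaled sorted uniforms, which samples the uniform non-overlapping
  arrangement exactly and never rejects. The analytic chance level
  `E(Dice) ≈ 2·o_A·o_B·T/(|A|+|B|)` ignores finite-size edge corrections
  of order (d_A+d_B)/T; at one-third occupancy in a 2-minute recording
  those corrections reach ~3%, so the calibration check runs in a sparse
  regime (~10% occupancy, 600 s) where the formula is accurate.
- Cross-correlogram lags use normalized cross-correlation within
  ±200 ms; positive lag means the first argument leads. Callers order
  channels by mediolateral coordinate (medial first) so the sign matches
  the propagation convention.
- Phase differences use the analytic-signal phase of theta-filtered
  traces with the waveform convention 0° = peak, −90° = ascending
  zero-crossing, ±180° = trough. Per qualifying co-theta period
  (frequency gate |Δf| < 0.01 Hz) the circular mean of the per-sample
  difference is taken; period-wise means are summarized by a Rayleigh
  test. The alternative — the phase at peak power — was not chosen
  because per-sample averaging uses the whole interval.
- Zero-variance degenerate inputs: regressions on a constant response
  return slope 0, r 0, p 1; a constant predictor is an error (it usually
  indicates a broken pipeline upstream). Identical frequency triplets
  give 1/CV² = ∞, a sentinel excluded (and counted) by the similarity
  regressions.
- The firing-rate analyses approximate a mixed model by
  standardize-then-pool: per cell, `log10(rate + 0.01)` across the cell's
  theta periods is Z-scored, as are theta power and frequency, and the
  standardized values are pooled into ordinary regressions. This is the
  pooling the headline analyses themselves describe; a random-intercept
  fit is a straightforward cross-check but not required by the pipeline.

The four statistics that drive headline results — Rayleigh, two-sample
Kuiper, Jonckheere–Terpstra (tie-corrected normal approximation, one-sided
increasing), two-sample KS — are implemented in the package and verified
against brute-force oracles (complex resultants, direct ECDF scans, full
pair enumeration) in the test suite. Extremely small p-values are clamped
at 1e-323. The asymptotic KS/Kuiper series are valid away from zero; for
λ below 0.3/0.4 the survival probability is 1 to double precision and is
returned as such. Note that two-sample KS p-values are inherently
discrete: at equal sample sizes the D lattice is coarse, so the null
calibration check uses coprime sample sizes (150 vs 131) where the
lattice is dense.

## The synthetic generator

`generate_dataset()` draws: (i) theta/non-theta epochs from an
alternating renewal process, durations 1 s + exponential (defaults: 5-s
theta epochs, 10-s gaps, i.e. a ~33% duty cycle matching the regime the
pipeline targets); (ii) a shared oscillator whose frequency performs a
reflected random walk inside 3–10 Hz (0.2 Hz/√s), gated by 100-ms
raised-cosine ramps; (iii) LFP channels as lagged copies of the shared
oscillator plus 1/f-amplitude pink noise (relative SD 0.3), supporting
per-channel mediolateral lags; (iv) per-cell theta_Vm as a convex mix of
the shared oscillator (weight `coupling_c`, with a per-cell phase offset)
and a private oscillator with its own epochs and frequency walk, on a
−60 mV baseline with 2-mV theta amplitude and white noise; (v) spikes as
per-cycle Bernoulli events at the theta_Vm peak with Gaussian phase
jitter (default SD 30°), rendered as 2-ms 80-mV triangular transients.
Reflection (not clipping) at the band edges keeps the frequency walk's
stationary distribution inside 3–10 Hz. A fixed seed reproduces the
dataset exactly.

What the generator does *not* emulate: gamma-band structure beyond pink
noise, conductance-based spike shapes, distance-dependent coupling,
state transitions other than the two-state renewal, and any dependence of
LFP *amplitude* on the cells. That last point matters for one analysis:
with the default composition (LFP = shared oscillator + noise) the LFP
theta power is constructionally independent of the cells' frequency
similarity, so the positive similarity–power association seen in real
triple recordings can only arise under the optional
`lfp_mode = "cell_mean"` composition (LFP = mean of the cells' theta
components + noise), where aligned cell frequencies add constructively.
Under that mode the association is positive at *every* coupling level —
the interference mechanism operates regardless of why frequencies align —
so passing tests demonstrate the machinery recovers the association, not
that coupling strength *per se* modulates it. This is a structural
property of the generator, not of real tissue.

## The waveform decoder

Architecture (fixed contract): 1-s theta-band Vm segments of 1–3 cells
(500 bins at 2 ms) pass through a 1-D convolution over time (64 filters,
kernel 9 bins = 18 ms, same padding, ReLU), flatten to 64 × 500 = 32,000,
a fully connected encoder 32,000 → 2,000 → 500 → 200 → 100 (ReLU,
dropout 0.5 after the non-bottleneck layers) and a fully connected
decoder 100 → 200 → 500 → 500 with a linear output. Endpoint sizes
(32,000 / 100 / 500) are the contract; the intermediate geometric
tapering is this package's choice. Loss is MSE, optimized by Adam
(lr 0.001, β₁ 0.9, β₂ 0.999, ε 1e-7, decay 1e-4). Training parameters
expose both published operating points — 50 epochs at lr 0.001, and the
tuning optimum of ~5 epochs at lr 0.01; short validation runs use ≤10
epochs.

Two numerical choices matter on layers this wide. First, inputs are
standardized per channel to SD 0.01 and targets to SD 1 (scales stored in
the model and inverted at prediction). Adam's early steps behave like
sign steps, so a layer of width 32,000 moves its output by roughly
`lr × width × E|activation|` per update; unit-scale activations overshoot
the targets within the first epoch and strand the ReLUs at a dead,
mean-predicting fixed point. Centimilli-scale inputs keep early updates
inside the target range. Second, the linear output layer is initialized
at 1/10 of He scale so the first epochs start from a near-zero prediction
rather than a large random one. With both, training loss decays smoothly
from ~1.0 (the variance of the standardized target) without a transient.

Evaluation: the recording is cut into 10 contiguous, equal, disjoint
blocks (recordings shorter than 3 min are rejected); training segments
slide within the nine training blocks, never crossing block boundaries;
test segments slide at 100 ms within the held-out block. The chance
control re-trains the same architecture from a fresh initialization on
within-cell segment-shuffled inputs (per-channel multisets preserved,
channel-to-target alignment destroyed; the shuffled arm re-initializes
with a derived seed rather than reusing the real arm's weights). Pooled
per-segment RMSE distributions are compared with the two-sample KS test.
Fold assignments, shuffles and segment sets are exactly reproducible
given a seed; network training additionally depends only on the seeded
C++ RNG and the BLAS in use.

## Validation scale

The validation experiments are sized for a single CPU: 2–5-minute
synthetic recordings; 640 training segments (10-ms stride, capped) and
~290 test segments per fold with ≤10 epochs for the decoder contrast;
20 seeds per condition for threshold-scan stability and the coupling
sweeps (the band-limited sweeps run at a 250-Hz analysis rate, which
changes nothing but compute); 10,000 surrogates for the Dice
calibration; 1,000 replicates for null p-value uniformity. The
acceptance script regenerates a 300-s two-LFP + three-cell study and
recomputes the headline quantities from scratch.

## Known limitations

- Theta-period *edges* carry a coherent, recording-level bias of up to
  one wavelet support (~0.5 s); membership (Dice) is far more accurate.
- The naive surrogate-Dice expectation is only asymptotically exact;
  expect percent-level deviations at high occupancy or short recordings.
- The similarity–power association has no mechanism to *increase* with
  the generator's coupling parameter under either LFP composition (see
  the generator section); the corresponding monotonicity check is
  therefore uninformative — a pass or fail of its 5-point rank trend
  reflects sampling variation, not a structural effect.
- `downsample_trace()` supports integer decimation factors only (the
  native 20 kHz → 500 Hz is factor 40).
- The decoder's absolute RMSE depends on how much of the target is
  in-band noise; only the real-vs-shuffled contrast is interpretable
  across datasets.
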