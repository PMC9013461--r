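---
title: "Methods: EAG response analysis and its synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EAG response analysis and its synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eagkit)
```

## The problem

Electroantennogram (EAG) recordings sum the receptor currents of an
insect antenna's olfactory receptor neurons into a single voltage
trace. Comparing EAG responses between groups — here, full-winged
(flighted) versus wing-reduced (flightless) ecotypes of a
wing-polymorphic stonefly — asks three questions per odorant and
population: is the response *weaker*, is it *slower* (later onset,
later offset), and can the antenna *track* rapidly fluctuating
stimuli? `eagkit` implements the full chain from raw stimulus-locked
voltage to those three answers, plus a synthetic generator that
produces recordings with known ground truth so every stage can be
validated quantitatively.

## The analysis chain

The order of operations is fixed, and matters:

1. **Segmentation.** Each stimulus yields a 5-s trace covering
   `[-0.2, 4.8)` s around valve opening. Windows are half-open and the
   sample at relative time 0 is the *first sample at or after* valve
   opening — a convention chosen to remove off-by-one ambiguity.
2. **Baseline correction** subtracts the median voltage of the
   pre-stimulus window `[-0.2, 0)` s. The window excludes t = 0, which
   may already contain stimulus.
3. **Median over repeats.** Each odorant/pulse-duration combination is
   presented 10 times; the pointwise median trace is robust to single
   outlier sweeps (a +100 mV artifact in 1 of 10 repeats leaves the
   median untouched). Even counts use the midpoint of the central
   order statistics.
4. **Running median, 11 ms.** Impulse noise shorter than half the
   window vanishes entirely. The filter runs *after* the
   median-of-repeats (the order the analysis prescribes), though the
   stage is a pure function and can be re-ordered for sensitivity
   checks. Edges use a shrinking window — the median over available
   samples — because inventing data at the boundary is worse, and all
   analysis windows sit far from the edges. Window/rate combinations
   that are not an odd integer number of samples are rejected, never
   silently rounded.

### Response metrics

* **Strength**: the mean over ±25 ms around the maximum between 50 ms
  and 1 s after valve opening (first occurrence on ties; the averaging
  window is clipped at trace edges rather than erroring).
* **Onset**: time of the final upward crossing of 10% of the maximum
  before the peak. The *last*-crossing reading is the default because
  an early noise blip that transiently exceeds 10% should not define
  the onset; the *first*-crossing variant is available
  (`response_onset(..., crossing = "first")`) since the definition
  "before signal maximum" admits both readings.
* **Offset**: the first sample after the peak at or below 10% of the
  maximum; a trace that never returns (e.g. plateaus at half maximum)
  yields an invalid offset, which the timing models exclude and count.
* **Pulse tracking**: a sine-taper multitaper power spectral density
  on the 3-s window starting 0.4 s after the first valve opening of a
  10-Hz train. Taper k at 0-based sample t is
  `sqrt(2/(N+1)) * sin(pi * k * (t+1)/(N+1))`; tapers are orthonormal
  to machine precision, and the one-sided density integrates to the
  windowed signal's variance (Parseval, verified to 1% on white
  noise). Five tapers by default: enough smoothing for the 1/3-Hz
  resolution without washing out a 10-Hz line. The `tracking_score`
  divides the 10-Hz density by the median density within ±3 Hz
  (excluding the 10-Hz bin): white noise scores ≈ 1, a tracking
  antenna scores ≫ 10.

### Quality control

An antenna enters the analysis only if the filtered median trace of
the *final* control block (ten 300-ms pulses of the first odorant,
presented at the end of the experiment) exceeds a response threshold —
twice the SD of the last 3 s of the trace — strictly, for at least 50
consecutive ms within 50–1000 ms after valve opening. Runs are whole
samples converted to ms; window endpoints are inclusive; runs are
clipped to the window before measuring. The 49-ms/50-ms boundary is
tested exactly.

A second screen flags sudden baseline shifts: medians of adjacent
0.5-s windows differing by more than 6 robust noise SDs (1.4826 × MAD
of the first-differenced signal). Since no quantitative definition of
a "sudden baseline shift" exists for the original recordings, the
parameters here are fixed by two requirements validated in the tests:
generator step artifacts of the documented magnitude (20 × noise SD)
landing between stimuli are always caught, and artifact-free
recordings are never flagged. Comparison windows are required not to
intersect `[-0.1, +1.5]` s around any stimulus onset — excluding only
the boundary point would let the decay tail of a strong genuine
response sit inside one window and trigger a false alarm. The cost,
stated plainly: a step inside a response zone can go undetected.

### Inference

Strength is modelled per odorant and population as

```
log2(strength + 0.01) ~ ecotype * duration + (1 | antenna)
```

with pulse duration a four-level categorical factor (reference 15 ms)
— the per-duration certainty labels imply per-level contrasts — and a
random intercept absorbing between-antenna amplitude variation. The
0.01 mV offset keeps weakly negative mean responses in the log domain
and is subtracted again after back-transformation. Onset and offset
times (300-ms pulses only) use `log2(time) ~ ecotype`; times are
strictly positive so no offset is added there — the offset sentence in
the source methods is written only for strength.

Uncertainty comes from flat-prior posterior simulation (10,000 draws):
for the linear model, residual variance from its scaled
inverse-chi-squared posterior, then coefficients from the
correspondingly scaled multivariate normal; for the mixed model,
fixed-effect draws conditional on the REML variance components — the
approximation used by `arm::sim`-style workflows, stated here as an
approximation (it ignores variance-component uncertainty; with ≥ 20
antennae the effect on interval coverage is within the tested ±4%).
The **certainty** of a contrast is the larger of the two directional
posterior proportions — deliberately direction-agnostic, so under the
null about 10% of contrasts earn an asterisk at the 0.95 cutoff (both
tails), which the calibration test confirms. One star above 0.95, two
above 0.99; no multiple-testing correction, matching the original
analysis (one model per odorant × population), and the direction is
always reported alongside.

## What the generator emulates — and what it does not

`generate_recording()` is a linear first-order cascade: valve state →
odorant concentration (first-order low-pass, rise constant during
opening, decay after closing — computed exactly from the closed-form
step response) → transduction latency → asymmetric first-order
antennal filter → gain, plus Gaussian noise, slow sinusoidal drift,
and optionally one step-like baseline shift. Wing-reduced antennae get
a multiplicative gain ratio and additive latency/decay increments.
This reproduces the *features the analysis relies on*: graded peak
concentration with pulse duration (concentration rise times exceed
150 ms, so a 15-ms opening reaches a lower peak than a 300-ms one),
positive-going excitatory deflections, realistic onset/offset
kinetics, drift that stresses baseline correction, and a fast
"honey-bee-like" preset (rise/decay ≤ 10 ms) that tracks 10-Hz trains
where the slow stonefly preset (τ ≥ 0.3 s) does not.

It does **not** model receptor adaptation, odorant-specific surface
interactions, spike generation, or any mechanistic OR/Orco chemistry.
A green test therefore establishes that the *pipeline* recovers what
the stated world contains — not that the world is a faithful stonefly.

Defaults the source material does not state, chosen once as realistic
for EAG work and then left alone: noise SD 0.1 mV against ~2 mV peak
responses (SNR ≈ 20), drift 0.2 mV over a 60-s period, between-antenna
SD of 0.4 on the log2-gain scale (≈ ±32% amplitude spread), residual
log2 SD 0.25 for the metrics-level simulator, artifact steps of 2 mV
(20 × noise SD). Amplitudes are arbitrary-scale millivolts: every
downstream statistic is ratio- or threshold-based.

Two simulation levels exist by design. Full-signal cohorts
(`generate_cohort()`) exercise everything from segmentation to PSD and
back the determinism, linearity, and kinetic-recovery tests.
Metrics-level cohorts (`simulate_metrics_table()`) draw strengths and
timings directly from the same generative parameters and feed the
calibration and parameter-recovery studies (hundreds of replicate
model fits), which would be hours of compute at the signal level with
no added coverage of the signal path.

## Numerical choices and degenerate inputs

* Seeds: every stochastic stage derives its seed by hashing the master
  seed with a stage/antenna key (kept below 2^31), so stages re-run
  independently and whole pipelines are byte-reproducible.
* `noise_sd = 0` is allowed and exact: noiseless fixtures give the
  analytic first-order crossing times within one sample period, and
  noiseless model fits recover coefficients to 1e-8 (the mixed model
  collapses to OLS with zero variance components).
* Ties in the peak search resolve to the first occurrence;
  threshold exceedance is strictly greater-than; the 10%-level
  comparisons are ≥ on the way up and ≤ on the way down.
* The train-spacing rule measures "10 s after the last 300-ms
  stimulus" from that stimulus's *onset*, and the next odorant starts
  5 s after the end of the 3-s train period.
* The ecotype "offset delay" acts on the antenna decay time constant
  in the signal generator (shifting the 10% return by ≈ delay × ln 10)
  and on the offset time itself in the metrics-level simulator.

## Known limitations

* The baseline-shift screen cannot see steps inside response zones.
* The mixed-model posterior conditions on estimated variance
  components; with very few antennae its intervals are slightly
  anti-conservative.
* Voltage serialization keeps 9 significant digits — beyond any
  amplifier's resolution, but round-trips are exact only to that
  precision.
* The generator's odorant kinetics are per-odorant constants; real
  stimulus dynamics are odorant- and device-surface-specific and are
  not modelled beyond the first-order rise/decay.
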