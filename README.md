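# eagkit

Analysis of electroantennogram (EAG) recordings for comparing
olfactory response strength, speed, and temporal resolution between
groups of insects — built around the comparison of full-winged
(flighted) versus wing-reduced (flightless) stonefly ecotypes, with a
synthetic-recording generator that provides ground truth for every
quantity the pipeline estimates.

## What it computes

From a continuous voltage recording plus a valve-event table, per
antenna × odorant × pulse duration:

* **Preprocessing** — 5-s stimulus-locked traces on `[-0.2, 4.8)` s,
  baseline-corrected by the pre-stimulus median, median-averaged over
  the 10 repeats of each stimulus, denoised with an 11-ms running
  median.
* **QC** — an antenna is analysed only if its final control response
  exceeds a threshold of 2 × SD(last 3 s) for ≥ 50 consecutive ms
  within 50–1000 ms after valve opening; a robust screen flags sudden
  baseline shifts.
* **Metrics** — response strength (mean over ±25 ms around the
  in-window maximum), onset and offset latency (10%-of-maximum
  crossings before/after the peak), and 10-Hz pulse tracking via a
  sine-taper multitaper power spectral density.
* **Inference** — per odorant: `log2(strength + 0.01) ~ ecotype *
  duration + (1 | antenna)` (REML, via lme4) and `log2(timing) ~
  ecotype` for 300-ms pulses, with flat-prior posterior simulation
  (10,000 draws), 95% credible intervals, direction-agnostic certainty
  proportions, and the `*` (> 0.95) / `**` (> 0.99) convention.

See `vignettes/eagkit-methods.Rmd` for the model, the assumptions, and
every numerical convention.

## Worked example

```r
library(eagkit)

cfg <- run_config(
  generator = eag_config(n_antennae = 2, noise_sd = 0.05),
  odorants = "2-heptanone", n_sim = 2000, seed = 1)
bundle <- run_pipeline(cfg)
cat(make_report(bundle), sep = "\n")
```

prints (numbers produced by this exact code):

```
EAG analysis report
===================
Antennae analysed: 4 of 4

Odorant: 2-heptanone
  strength   15 ms: log2(WR/FW) = -1.102 [-1.228, -0.980], certainty 1.000 **
  strength   30 ms: log2(WR/FW) = -1.191 [-1.314, -1.063], certainty 1.000 **
  strength  150 ms: log2(WR/FW) = -1.236 [-1.368, -1.114], certainty 1.000 **
  strength  300 ms: log2(WR/FW) = -1.242 [-1.368, -1.120], certainty 1.000 **
  onset    300 ms: log2(WR/FW) = +0.738 [+0.667, +0.812], certainty 1.000 **
  offset   300 ms: log2(WR/FW) = +0.052 [-0.018, +0.128], certainty 0.957 *
```

Reading it: the wing-reduced antennae of this synthetic cohort respond
at roughly 2^-1.2 ≈ 43% of the full-winged amplitude at every pulse
duration (the generator's true cohort ratio is 2^-0.5, drawn with
between-antenna spread at n = 2 per ecotype), their onset is ≈ 2^0.74
≈ 1.7× later, and each contrast carries its credible interval and
certainty stars. The same bundle holds the per-antenna QC table
(`bundle$qc`), the metrics table (`bundle$metrics`), 10-Hz tracking
scores (`bundle$tracking` — the slow stonefly-like preset scores ≈ 1,
i.e. no tracking; the fast honey-bee-like preset scores ≫ 10), and a
ground-truth recovery table for synthetic runs (`bundle$recovery`).

A command-line wrapper lives at `inst/cli/eagkit.R`:

```sh
Rscript inst/cli/eagkit.R simulate --n 10 --seed 1 --out recs/
Rscript inst/cli/eagkit.R run --n 10 --seed 1 --out results/
```

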