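## Shared fixtures: all built in code, nothing on disk.

## standard 5-s trace from a voltage function of relative time
fn_trace <- function(f, fs = 1000, prov = list(antenna_id = "t",
                                               odorant = "o",
                                               pulse_ms = 300,
                                               repeat_index = 1)) {
  n <- 5 * fs
  tt <- (seq_len(n) - 1 - 0.2 * fs) / fs
  eag_trace(f(tt), fs, prov)
}

flat_trace <- function(value = 0, fs = 1000) fn_trace(function(t)
  rep(value, length(t)), fs)

## first-order response kernel with closed-form 10%-crossing times:
## zero until `latency`, rises as 1 - exp(-(t - latency)/tau_r) while
## the valve is open (`open` s), then decays exponentially with tau_d.
kernel_trace <- function(latency, tau_r, tau_d, open = 0.3, gain = 1,
                         fs = 1000) {
  M_rel <- 1 - exp(-open / tau_r)
  tr <- fn_trace(function(t) {
    v <- numeric(length(t))
    ris <- t >= latency & t <= latency + open
    dec <- t > latency + open
    v[ris] <- gain * (1 - exp(-(t[ris] - latency) / tau_r))
    v[dec] <- gain * M_rel * exp(-(t[dec] - latency - open) / tau_d)
    v
  }, fs)
  attr(tr, "onset_true") <- latency - tau_r * log(1 - 0.1 * M_rel)
  attr(tr, "offset_true") <- latency + open + tau_d * log(10)
  attr(tr, "peak_true") <- latency + open
  tr
}

## O(n * w log w) brute-force running median with the shrinking-window
## edge rule
brute_runmed <- function(x, k) {
  h <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n),
         function(i) median(sort(x[max(1L, i - h):min(n, i + h)])),
         numeric(1))
}

## small cohort config for fast end-to-end tests
tiny_cfg <- function(..., n_antennae = 2, rng_seed = 11) {
  eag_config(n_antennae = n_antennae, rng_seed = rng_seed, ...)
}

## minimal hand-built posterior object for summarize_comparison tests
fake_posterior <- function(delta, intercept = 0) {
  draws <- cbind("(Intercept)" = rep(intercept, length(delta)),
                 "ecotypewing-reduced" = delta)
  structure(list(draws = draws, sigma = rep(1, length(delta)),
                 type = "lm", response = "onset", offset = 0,
                 durations = "300"),
            class = "eag_posterior")
}

## tiny 3-sample recording with one event, for io round trips
tiny_recording <- function(voltage = c(1.25, -0.5, 0.75)) {
  eag_recording(antenna_id = "t01", ecotype = "full-winged",
                population = "testpop", sampling_rate = 1000, t0 = 0,
                voltage = voltage,
                events = data.frame(onset_s = 0.001, valve_open_s = 0.0005,
                                    odorant = "2-heptanone", block = "main",
                                    repeat_index = 1L))
}
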