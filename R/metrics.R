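## metrics: response strength, onset/offset latency, multitaper PSD and
## 10-Hz pulse-tracking score.

## samples eligible as "the maximum signal between 50 ms and 1 s after
## valve opening" (endpoints inclusive)
.search_window <- function(trace) {
  which(trace$time >= 0.05 - .time_eps & trace$time <= 1.0 + .time_eps)
}

.window_max <- function(trace) {
  idx <- .search_window(trace)
  i <- idx[which.max(trace$voltage[idx])]   # first occurrence on ties
  list(i = i, t = trace$time[i], M = trace$voltage[i])
}

#' Response strength
#'
#' Mean response in the window from 25 ms before to 25 ms after the
#' maximum signal between 50 ms and 1 s after valve opening. The first
#' occurrence is used when the maximum is tied; the +-25 ms window is
#' clipped to the trace. May be negative for inhibitory traces.
#'
#' @param trace a filtered median [eag_trace()].
#' @return strength in mV.
#' @export
response_strength <- function(trace) {
  mx <- .window_max(trace)
  sel <- trace$time >= mx$t - 0.025 - .time_eps &
    trace$time <= mx$t + 0.025 + .time_eps
  mean(trace$voltage[sel])
}

#' Response onset time
#'
#' Time between valve opening and the signal's crossing of 10% of its
#' maximum, before the maximum. With `crossing = "last"` (default) the
#' onset is the first sample of the last contiguous run of samples at
#' or above the 10% level that ends at the maximum — i.e. the final
#' upward crossing before the peak, robust to early noise blips;
#' `crossing = "first"` takes the first sample at/after valve opening
#' that reaches the level. Onset is never reported before valve
#' opening (t = 0).
#'
#' @param trace a filtered median [eag_trace()].
#' @param crossing `"last"` or `"first"` upward 10%-crossing.
#' @return onset in seconds, or `NA_real_` (invalid) when the window
#'   maximum is not positive.
#' @export
response_onset <- function(trace, crossing = c("last", "first")) {
  crossing <- match.arg(crossing)
  mx <- .window_max(trace)
  if (mx$M <= 0) return(NA_real_)
  level <- 0.1 * mx$M
  i_zero <- which(trace$time >= -.time_eps)[1]  # first sample at/after t = 0
  idx <- i_zero:mx$i
  at_level <- trace$voltage[idx] >= level
  if (crossing == "first") {
    j <- which(at_level)[1]
    return(trace$time[idx[j]])
  }
  ## last contiguous run ending at the maximum
  j <- length(idx)
  while (j > 1L && at_level[j - 1L]) j <- j - 1L
  trace$time[idx[j]]
}

#' Response offset time
#'
#' Time between valve opening and the signal's return to 10% of its
#' maximum after the maximum: the first sample after the peak with
#' value at or below the 10% level, searched to the end of the trace.
#'
#' @param trace a filtered median [eag_trace()].
#' @return offset in seconds, or `NA_real_` (invalid) when the maximum
#'   is not positive or the level is never reached again.
#' @export
response_offset <- function(trace) {
  mx <- .window_max(trace)
  if (mx$M <= 0) return(NA_real_)
  level <- 0.1 * mx$M
  n <- length(trace$voltage)
  if (mx$i >= n) return(NA_real_)
  idx <- (mx$i + 1L):n
  j <- which(trace$voltage[idx] <= level)[1]
  if (is.na(j)) return(NA_real_)
  trace$time[idx[j]]
}

#' All scalar response metrics of a trace
#'
#' @param trace a filtered median [eag_trace()].
#' @return one-row data.frame: `strength_mV`, `onset_s`, `offset_s`,
#'   `peak_time_s` plus the trace provenance columns.
#' @export
response_metrics <- function(trace) {
  mx <- .window_max(trace)
  p <- trace$provenance
  data.frame(antenna_id = p$antenna_id %||% NA_character_,
             odorant = p$odorant %||% NA_character_,
             pulse_duration_ms = p$pulse_ms %||% NA_real_,
             strength_mV = response_strength(trace),
             onset_s = response_onset(trace),
             offset_s = response_offset(trace),
             peak_time_s = mx$t)
}

#' Sine tapers
#'
#' The orthonormal sine-taper family: taper `k` (1-based) evaluated at
#' sample `t` (0-based) is `sqrt(2 / (N + 1)) * sin(pi * k * (t + 1) /
#' (N + 1))`.
#'
#' @param n_samples window length N.
#' @param k_tapers number of tapers (`1 <= k < N`).
#' @return `n_samples` x `k_tapers` matrix; columns have unit sum of
#'   squares and are mutually orthogonal.
#' @export
sine_tapers <- function(n_samples, k_tapers) {
  if (k_tapers < 1 || k_tapers >= n_samples)
    stop_config("k_tapers must satisfy 1 <= k < n_samples")
  t <- seq_len(n_samples)  # t + 1 for 0-based t
  sapply(seq_len(k_tapers), function(k)
    sqrt(2 / (n_samples + 1)) * sin(pi * k * t / (n_samples + 1)))
}

#' Sine-taper multitaper power spectral density
#'
#' One-sided PSD of a 3-s window, averaged over `k_tapers` sine tapers,
#' in density units (power per Hz) so that the integral of the PSD over
#' `[0, fs/2]` approximates the variance of the (mean-removed) window.
#' Frequency resolution is 1/3 Hz for the 3-s window.
#'
#' @param x numeric window of exactly `3 * sampling_rate` samples; for
#'   the pulse-tracking analysis this is the stretch of the filtered
#'   train trace starting 0.4 s after the first valve opening (see
#'   [train_window()]). The mean is removed before tapering.
#' @param sampling_rate Hz.
#' @param k_tapers number of sine tapers (default 5).
#' @return object of class `eag_psd`: list with `frequency` (Hz, from 0
#'   to `sampling_rate / 2`), `density` (mV^2/Hz), `k_tapers`.
#' @export
multitaper_psd <- function(x, sampling_rate, k_tapers = 5) {
  n <- as.integer(round(3 * sampling_rate))
  if (length(x) != n)
    stop("PSD window must be exactly 3 s = ", n, " samples, got ", length(x))
  x <- x - mean(x)
  tap <- sine_tapers(n, k_tapers)
  nf <- n %/% 2L + 1L
  dens <- numeric(nf)
  for (k in seq_len(k_tapers)) {
    Y <- fft(tap[, k] * x)
    P <- Mod(Y[seq_len(nf)])^2 / sampling_rate   # two-sided density
    P[2:(nf - 1L)] <- 2 * P[2:(nf - 1L)]          # fold onto [0, fs/2]
    dens <- dens + P
  }
  structure(list(frequency = (seq_len(nf) - 1) * sampling_rate / n,
                 density = dens / k_tapers,
                 k_tapers = k_tapers),
            class = "eag_psd")
}

#' Extract the PSD window from a train trace
#'
#' The pulse-tracking PSD is computed on a 3-s window starting 0.4 s
#' after the first valve opening of the 10-Hz train; on the standard
#' trace grid that is relative time `[0.4, 3.4)` s.
#'
#' @param trace the filtered train [eag_trace()] segmented at the first
#'   train opening.
#' @return numeric vector of `3 * sampling_rate` samples.
#' @export
train_window <- function(trace) {
  sel <- trace$time >= 0.4 - .time_eps & trace$time < 3.4 - .time_eps
  trace$voltage[sel]
}

#' 10-Hz pulse-tracking score
#'
#' Ratio of the spectral density at the stimulation frequency to the
#' median density over the surrounding band (`f0 +- half_band` Hz,
#' excluding the `f0` bin). Scores much larger than 1 indicate that the
#' antenna tracks the pulse train; white noise gives a score near 1.
#'
#' @param psd an `eag_psd` from [multitaper_psd()].
#' @param f0 stimulation frequency (Hz); must lie on the frequency
#'   grid.
#' @param half_band half-width (Hz) of the reference band.
#' @return dimensionless ratio.
#' @export
tracking_score <- function(psd, f0 = 10, half_band = 3) {
  i0 <- which(abs(psd$frequency - f0) < 1e-9)
  if (length(i0) != 1L)
    stop_config("f0 = ", f0, " Hz is not on the frequency grid")
  band <- which(abs(psd$frequency - f0) <= half_band + 1e-9)
  band <- setdiff(band, i0)
  psd$density[i0] / median(psd$density[band])
}
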