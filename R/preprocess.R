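## preprocess: recording -> baseline-corrected, denoised, repeat-median
## stimulus-locked traces. Pipeline order is fixed:
## segment -> baseline_correct -> median_over_repeats -> running_median.

#' Stimulus-locked trace
#'
#' A 5-s trace on the fixed relative-time grid `[-0.2 s, 4.8 s)` at the
#' recording's sampling rate (exactly `5 * fs` samples).
#'
#' @param voltage numeric voltage (mV), `5 * sampling_rate` samples.
#' @param sampling_rate Hz.
#' @param provenance list: `antenna_id`, `odorant`, `pulse_ms`,
#'   `repeat_index` (an integer, or `"median"` after averaging).
#' @return object of class `eag_trace` with elements `time` (relative
#'   seconds), `voltage`, `sampling_rate`, `provenance`.
#' @export
eag_trace <- function(voltage, sampling_rate, provenance = list()) {
  n <- as.integer(round(5 * sampling_rate))
  if (length(voltage) != n)
    stop("trace must have exactly 5 s x sampling_rate = ", n, " samples")
  pre <- as.integer(round(0.2 * sampling_rate))
  structure(list(time = (seq_len(n) - 1 - pre) / sampling_rate,
                 voltage = as.numeric(voltage),
                 sampling_rate = sampling_rate,
                 provenance = provenance),
            class = "eag_trace")
}

#' @export
print.eag_trace <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<eag_trace> %s %s %s ms rep %s: [-0.2, 4.8) s at %g Hz\n",
              p$antenna_id %||% "?", p$odorant %||% "?",
              p$pulse_ms %||% "?", p$repeat_index %||% "?",
              x$sampling_rate))
  invisible(x)
}

#' Cut one stimulus-locked trace out of a recording
#'
#' Extracts the half-open window `[onset - 0.2 s, onset + 4.8 s)`; the
#' sample at relative time 0 is the first sample at or after valve
#' opening. Samples are copied verbatim (no interpolation).
#'
#' @param recording an [eag_recording()].
#' @param event one row of the recording's event table (data.frame or
#'   list with `onset_s`, `valve_open_s`, `odorant`, `repeat_index`).
#' @return an [eag_trace()].
#' @export
segment_trace <- function(recording, event) {
  fs <- recording$sampling_rate
  pre <- 0.2 * fs
  if (abs(pre - round(pre)) > 1e-6)
    stop_config("0.2 s pre-stimulus window is not an integer number of ",
                "samples at ", fs, " Hz")
  pre <- as.integer(round(pre))
  n_out <- as.integer(round(5 * fs))
  ## 1-based index of the first sample at/after onset
  i0 <- as.integer(ceiling((event$onset_s - recording$t0) * fs - .time_eps)) + 1L
  start <- i0 - pre
  end <- start + n_out - 1L
  if (start < 1L || end > length(recording$voltage))
    stop(sprintf(
      "event at %g s (odorant %s, repeat %s) does not fit the recording",
      event$onset_s, event$odorant, event$repeat_index))
  eag_trace(recording$voltage[start:end], fs,
            provenance = list(antenna_id = recording$antenna_id,
                              odorant = event$odorant,
                              pulse_ms = round(event$valve_open_s * 1000),
                              repeat_index = event$repeat_index,
                              block = event$block %||% NA))
}

#' Baseline-correct a trace
#'
#' Subtracts the median voltage of the pre-stimulus window (relative
#' time in `[-0.2, 0)` s, excluding t = 0 which may already contain
#' stimulus) from the entire trace. Idempotent.
#'
#' @param trace an [eag_trace()].
#' @return the corrected [eag_trace()].
#' @export
baseline_correct <- function(trace) {
  base <- median(trace$voltage[trace$time < -.time_eps])
  trace$voltage <- trace$voltage - base
  trace
}

#' Pointwise median over repeated stimulations
#'
#' Median trace over a set of same-stimulus traces (normally the 10
#' repeats of one odorant/pulse-duration combination). For even counts
#' the midpoint of the two central order statistics is used. The
#' result's provenance is marked `repeat_index = "median"`.
#'
#' @param traces list of [eag_trace()] objects sharing grid and
#'   stimulus identity (odorant and pulse duration).
#' @return an [eag_trace()].
#' @export
median_over_repeats <- function(traces) {
  stopifnot(length(traces) >= 1)
  p1 <- traces[[1]]$provenance
  for (tr in traces) {
    if (!identical(tr$provenance$odorant, p1$odorant) ||
        !identical(tr$provenance$pulse_ms, p1$pulse_ms))
      stop("cannot take the median over traces of mixed stimulus identity")
    if (tr$sampling_rate != traces[[1]]$sampling_rate)
      stop("cannot take the median over traces with different grids")
  }
  mat <- vapply(traces, function(tr) tr$voltage,
                numeric(length(traces[[1]]$voltage)))
  med <- apply(mat, 1, median)
  prov <- p1
  prov$repeat_index <- "median"
  eag_trace(med, traces[[1]]$sampling_rate, prov)
}

#' Running median filter
#'
#' Centered running median with a window of `window_ms` milliseconds
#' (11 ms by default, i.e. 11 samples at 1 kHz). The window must be an
#' odd number of samples at the trace's rate; non-integer combinations
#' are rejected rather than rounded. At the edges the window shrinks to
#' the available samples (no data are invented); edges lie outside
#' every analysis window.
#'
#' @param trace an [eag_trace()], or a bare numeric vector.
#' @param window_ms window length in ms.
#' @return filtered object of the same type as the input.
#' @export
running_median <- function(trace, window_ms = 11) {
  x <- if (inherits(trace, "eag_trace")) trace$voltage else trace
  fs <- if (inherits(trace, "eag_trace")) trace$sampling_rate else 1000
  k <- window_ms * fs / 1000
  if (abs(k - round(k)) > 1e-8)
    stop_config("window of ", window_ms, " ms is not an integer number of ",
                "samples at ", fs, " Hz")
  k <- as.integer(round(k))
  if (k %% 2L == 0L)
    stop_config("running median window must be an odd number of samples, got ",
                k)
  n <- length(x)
  if (k >= 3L && n >= k) {
    y <- as.numeric(stats::runmed(x, k, endrule = "keep"))
    h <- (k - 1L) %/% 2L
    for (i in c(seq_len(h), seq.int(n - h + 1L, n)))
      y[i] <- median(x[max(1L, i - h):min(n, i + h)])
  } else {
    h <- (k - 1L) %/% 2L
    y <- vapply(seq_len(n),
                function(i) median(x[max(1L, i - h):min(n, i + h)]),
                numeric(1))
  }
  if (inherits(trace, "eag_trace")) {
    trace$voltage <- y
    trace
  } else y
}

#' Preprocess a whole recording
#'
#' Applies the fixed pipeline (segment, baseline-correct, median over
#' the 10 repeats, 11-ms running median) to every stimulus set of a
#' recording. The 10-Hz train is segmented once at its first valve
#' opening (it has no repeats to median over) and the final control
#' block is processed like a main-series set.
#'
#' @param recording an [eag_recording()].
#' @param window_ms running median window (ms).
#' @return list with `stimuli` (list of filtered median [eag_trace()]s,
#'   one per odorant x pulse-duration set, named `"odorant/ms"`),
#'   `control` (filtered median trace of the final control block, or
#'   `NULL` if absent) and `trains` (named list of filtered train
#'   traces, one per odorant).
#' @export
preprocess_recording <- function(recording, window_ms = 11) {
  ev <- recording$events
  out <- list(stimuli = list(), control = NULL, trains = list())
  main <- ev[ev$block == "main", , drop = FALSE]
  if (nrow(main)) {
    keys <- unique(main[, c("odorant", "valve_open_s")])
    for (j in seq_len(nrow(keys))) {
      sel <- main[main$odorant == keys$odorant[j] &
                    main$valve_open_s == keys$valve_open_s[j], ,
                  drop = FALSE]
      traces <- lapply(seq_len(nrow(sel)), function(i)
        baseline_correct(segment_trace(recording, sel[i, ])))
      med <- running_median(median_over_repeats(traces), window_ms)
      out$stimuli[[paste0(keys$odorant[j], "/",
                          round(keys$valve_open_s[j] * 1000))]] <- med
    }
  }
  ctrl <- ev[ev$block == "control", , drop = FALSE]
  if (nrow(ctrl)) {
    traces <- lapply(seq_len(nrow(ctrl)), function(i)
      baseline_correct(segment_trace(recording, ctrl[i, ])))
    out$control <- running_median(median_over_repeats(traces), window_ms)
  }
  trn <- ev[ev$block == "train", , drop = FALSE]
  for (od in unique(trn$odorant)) {
    first <- trn[trn$odorant == od, , drop = FALSE][1, ]
    tr <- running_median(baseline_correct(segment_trace(recording, first)),
                         window_ms)
    out$trains[[od]] <- tr
  }
  out
}
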