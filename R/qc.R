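## qc: responsiveness criterion and baseline-shift screen.

#' Response threshold of a median trace
#'
#' Twice the standard deviation of the last 3 s of the 5-s trace
#' (relative time in `[1.8, 4.8)` s). Invariant to adding a constant to
#' the whole trace.
#'
#' @param trace an [eag_trace()] (normally the filtered median trace).
#' @return threshold in mV.
#' @export
response_threshold <- function(trace) {
  tail_v <- trace$voltage[trace$time >= 1.8 - .time_eps]
  2 * sd(tail_v)
}

#' Detect a stimulus-locked response
#'
#' An antenna responds if the trace exceeds the threshold (strictly)
#' for at least 50 consecutive ms within relative time
#' `[0.05, 1.0]` s after valve opening (window endpoints inclusive; a
#' run is measured in whole samples and converted to ms). Runs are
#' clipped to the window before their length is measured.
#'
#' @param trace an [eag_trace()].
#' @param threshold mV, typically from [response_threshold()].
#' @return list with `responsive` (logical) and `longest_exceedance_ms`.
#' @export
detect_response <- function(trace, threshold) {
  stopifnot(threshold >= 0)
  sel <- trace$time >= 0.05 - .time_eps & trace$time <= 1.0 + .time_eps
  above <- trace$voltage[sel] > threshold
  longest <- 0L
  if (any(above)) {
    r <- rle(above)
    longest <- max(r$lengths[r$values])
  }
  ms <- longest * 1000 / trace$sampling_rate
  list(responsive = ms >= 50 - .time_eps, longest_exceedance_ms = ms)
}

#' QC decision for one antenna
#'
#' Applies the responsiveness criterion to the filtered median trace of
#' the final control block (ten 300-ms stimulations of the control
#' odorant presented at the end of the experiment): if that trace does
#' not exceed its response threshold for at least 50 consecutive ms
#' between 50 and 1000 ms after valve opening, all recordings from the
#' antenna are excluded. The decision is a pure function of the control
#' trace.
#'
#' @param control_trace filtered median [eag_trace()] of the final
#'   control block; `NULL` or missing is a QC error.
#' @param antenna_id id copied into the result.
#' @return one-row data.frame: `antenna_id`, `responsive`,
#'   `threshold_mV`, `longest_exceedance_ms`, `baseline_shift_detected`
#'   (`NA`, filled by the pipeline), `decision`, `reason`.
#' @export
qc_antenna <- function(control_trace, antenna_id = NULL) {
  if (is.null(control_trace))
    stop("missing final control block: cannot run responsiveness QC")
  thr <- response_threshold(control_trace)
  det <- detect_response(control_trace, thr)
  id <- antenna_id %||% control_trace$provenance$antenna_id %||% NA_character_
  data.frame(antenna_id = id,
             responsive = det$responsive,
             threshold_mV = thr,
             longest_exceedance_ms = det$longest_exceedance_ms,
             baseline_shift_detected = NA,
             decision = if (det$responsive) "include" else "exclude",
             reason = if (det$responsive) "" else "unresponsive")
}

#' Screen a recording for sudden baseline shifts
#'
#' Compares the medians of adjacent `window_s`-long windows sliding
#' along the recording; a shift is flagged where their absolute
#' difference exceeds `k` times a robust noise scale (1.4826 x median
#' absolute deviation of the first-differenced signal). Boundary
#' positions whose windows would intersect the response zone
#' `[-0.1, +1.5]` s around any stimulus onset are skipped so that
#' genuine odorant responses (including their decay tails) are not
#' mistaken for artifacts; a step falling entirely inside a response
#' zone can therefore go undetected. Invariant to adding a constant to
#' the recording.
#'
#' Defaults (`k = 6`, `window_s = 0.5`) are tuned so that step
#' artifacts of the magnitude produced by the generator (20 x noise SD)
#' are always caught while artifact-free recordings are not flagged.
#'
#' @param recording an [eag_recording()].
#' @param k detection threshold in robust-noise-SD units.
#' @param window_s half-window length in seconds.
#' @param stride_s spacing of tested boundary positions (default
#'   `window_s / 5`).
#' @return logical: `TRUE` if a baseline shift was detected.
#' @export
detect_baseline_shift <- function(recording, k = 6, window_s = 0.5,
                                  stride_s = window_s / 5) {
  fs <- recording$sampling_rate
  n <- length(recording$voltage)
  if (n <= 2 * window_s * fs)
    stop("recording shorter than two windows")
  w <- as.integer(round(window_s * fs))
  sigma <- mad(diff(recording$voltage))
  if (sigma == 0) sigma <- .Machine$double.eps
  onsets <- recording$events$onset_s
  tt0 <- recording$t0
  stride <- max(1L, as.integer(round(stride_s * fs)))
  bounds <- seq.int(w + 1L, n - w, by = stride)
  b_time <- tt0 + (bounds - 1) / fs
  if (length(onsets)) {
    ## exclude boundaries whose [b - w, b + w] span intersects the
    ## response zone [onset - 0.1, onset + 1.5] of any stimulus
    near <- vapply(b_time, function(b)
      any(b + window_s > onsets - 0.1 - .time_eps &
            b - window_s < onsets + 1.5 + .time_eps),
      logical(1))
    bounds <- bounds[!near]
  }
  for (b in bounds) {
    m1 <- median(recording$voltage[(b - w):(b - 1L)])
    m2 <- median(recording$voltage[b:(b + w - 1L)])
    if (abs(m2 - m1) > k * sigma) return(TRUE)
  }
  FALSE
}
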