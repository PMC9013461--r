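## signal_io: on-disk representation of recordings.
##
## One recording = three plain-text files sharing the antenna id as
## prefix:
##   <id>.trace.csv   time_s, voltage_mV  (9 significant digits)
##   <id>.events.csv  onset_s, valve_open_s, odorant, block, repeat_index
##   <id>.meta.json   antenna_id, ecotype, population, sampling_rate, t0

#' Construct an EAG recording
#'
#' @param antenna_id character id, used as the file prefix on disk.
#' @param ecotype `"full-winged"`, `"wing-reduced"` or `"reference"`
#'   (the latter for non-stonefly scale antennae such as honey bees).
#' @param population collection-site label.
#' @param sampling_rate Hz, > 0.
#' @param t0 absolute time (s) of the first voltage sample.
#' @param voltage numeric vector of uniformly sampled voltage (mV).
#' @param events data.frame with columns `onset_s`, `valve_open_s`,
#'   `odorant`, `block`, `repeat_index`.
#' @return object of class `eag_recording`.
#' @seealso [validate_recording()], [write_recording()],
#'   [read_recording()]
#' @export
eag_recording <- function(antenna_id, ecotype, population, sampling_rate,
                          t0, voltage, events) {
  rec <- structure(list(antenna_id = as.character(antenna_id),
                        ecotype = as.character(ecotype),
                        population = as.character(population),
                        sampling_rate = as.numeric(sampling_rate),
                        t0 = as.numeric(t0),
                        voltage = as.numeric(voltage),
                        events = as.data.frame(events)),
                   class = "eag_recording")
  issues <- validate_recording(rec)
  if (length(issues))
    stop("invalid recording: ", paste(issues, collapse = "; "))
  rec
}

#' @export
print.eag_recording <- function(x, ...) {
  dur <- length(x$voltage) / x$sampling_rate
  cat(sprintf("<eag_recording> %s (%s, %s): %.1f s at %g Hz, %d events\n",
              x$antenna_id, x$ecotype, x$population, dur, x$sampling_rate,
              nrow(x$events)))
  invisible(x)
}

#' Validate a recording against its invariants
#'
#' Never raises on bad data; returns a character vector of issues,
#' empty when all invariants hold. Checked: non-empty voltage, positive
#' sampling rate, required event columns, ascending event onsets,
#' events inside the recorded interval, and repeat index in 1..10 for
#' main and control blocks.
#'
#' @param recording an `eag_recording` (or structurally similar list).
#' @return character vector of human-readable issues; `character(0)`
#'   when valid.
#' @export
validate_recording <- function(recording) {
  issues <- character(0)
  add <- function(...) issues <<- c(issues, paste0(...))
  r <- recording
  if (length(r$voltage) < 1) add("voltage must have at least one sample")
  if (!is.numeric(r$sampling_rate) || length(r$sampling_rate) != 1 ||
      r$sampling_rate <= 0) {
    add("sampling_rate must be a positive scalar")
    return(issues)
  }
  ev <- r$events
  need <- c("onset_s", "valve_open_s", "odorant", "block", "repeat_index")
  miss <- setdiff(need, names(ev))
  if (length(miss)) {
    add("event table lacks column(s): ", paste(miss, collapse = ", "))
    return(issues)
  }
  if (nrow(ev) > 1 && any(diff(ev$onset_s) <= 0)) {
    bad <- which(diff(ev$onset_s) <= 0)[1] + 1L
    add("event onsets not strictly increasing at row ", bad)
  }
  t_end <- r$t0 + length(r$voltage) / r$sampling_rate
  out <- which(ev$onset_s < r$t0 - .time_eps |
                 ev$onset_s > t_end + .time_eps)
  if (length(out))
    add("event onset outside recording at row ", out[1])
  mc <- ev$block %in% c("main", "control")
  bad_rep <- which(mc & (ev$repeat_index < 1 | ev$repeat_index > 10))
  if (length(bad_rep))
    add("repeat_index outside 1..10 at row ", bad_rep[1])
  issues
}

#' Write a recording to disk
#'
#' Emits `<id>.trace.csv`, `<id>.events.csv` and `<id>.meta.json` under
#' `dir`. Voltage and time are serialized with 9 significant digits,
#' which exceeds the float32 precision of any plausible amplifier; the
#' time column is redundant with (`t0`, `sampling_rate`) but retained
#' for human inspection.
#'
#' @param recording an [eag_recording()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- recording$antenna_id
  paths <- file.path(dir, paste0(id, c(".trace.csv", ".events.csv",
                                       ".meta.json")))
  n <- length(recording$voltage)
  tt <- recording$t0 + (seq_len(n) - 1) / recording$sampling_rate
  tr <- data.frame(time_s = formatC(tt, format = "g", digits = 9),
                   voltage_mV = formatC(recording$voltage, format = "g",
                                        digits = 9))
  write.csv(tr, paths[1], row.names = FALSE, quote = FALSE)
  write.csv(recording$events, paths[2], row.names = FALSE)
  meta <- list(antenna_id = recording$antenna_id,
               ecotype = recording$ecotype,
               population = recording$population,
               sampling_rate = recording$sampling_rate,
               t0 = recording$t0)
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a recording written by [write_recording()]
#'
#' Rebuilds the `eag_recording` from the three files, trusting the
#' metadata sidecar for the time base and checking the redundant time
#' column against it: any sample whose timestamp deviates from the
#' uniform grid by more than `tol` seconds, or a sampling-rate mismatch
#' between the sidecar and the column spacing, is a format error naming
#' the offending row. Unsorted event tables are rejected likewise.
#'
#' @param dir directory containing the file set.
#' @param antenna_id file prefix.
#' @param tol time-grid tolerance in seconds.
#' @return an [eag_recording()].
#' @export
read_recording <- function(dir, antenna_id, tol = 1e-6) {
  paths <- file.path(dir, paste0(antenna_id, c(".trace.csv", ".events.csv",
                                               ".meta.json")))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing recording file(s): ", paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  tr <- read.csv(paths[1])
  ev <- read.csv(paths[2])
  n <- nrow(tr)
  grid <- meta$t0 + (seq_len(n) - 1) / meta$sampling_rate
  dev <- abs(tr$time_s - grid)
  if (any(dev > tol)) {
    bad <- which(dev > tol)[1]
    stop(sprintf(
      "non-uniform time grid in %s at row %d: %.9g s vs expected %.9g s",
      paths[1], bad, tr$time_s[bad], grid[bad]))
  }
  if (nrow(ev) > 1 && any(diff(ev$onset_s) <= 0)) {
    bad <- which(diff(ev$onset_s) <= 0)[1] + 1L
    stop(sprintf("event table %s not sorted by onset at row %d",
                 paths[2], bad))
  }
  eag_recording(antenna_id = meta$antenna_id, ecotype = meta$ecotype,
                population = meta$population,
                sampling_rate = meta$sampling_rate, t0 = meta$t0,
                voltage = tr$voltage_mV, events = ev)
}
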