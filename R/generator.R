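## synthetic_data: EAG recording generator with ground truth.

#' Generator configuration
#'
#' Builds the validated configuration object that drives the synthetic
#' EAG generator. Defaults describe a "stonefly-like" slow antenna; the
#' `"honeybee"` preset gives the fast antenna used for pulse-tracking
#' contrasts (rise/decay time constants at or below 10 ms).
#'
#' All absolute amplitudes are arbitrary-scale millivolts: every
#' downstream statistic is ratio- or threshold-based, so only relative
#' amplitudes matter. Noise, drift and between-antenna variability are
#' stated assumptions (they are not reported quantities for real
#' recordings); see the package vignette for the rationale behind each
#' default.
#'
#' @param sampling_rate sampling rate in Hz. Default 1000, so one sample
#'   is one millisecond and the 11-ms running median window is an
#'   integer number of samples.
#' @param odorant_kinetics named list of `list(rise, decay)` first-order
#'   time constants (s) describing odorant concentration dynamics at the
#'   stimulator outlet. Concentration rise times exceed 150 ms, so
#'   short valve openings reach lower peak concentrations than long
#'   ones.
#' @param antenna_kinetics `list(latency, rise, decay, gain)`:
#'   transduction latency (s), rise and decay time constants (s) of the
#'   antennal response, and gain in mV per unit concentration.
#' @param ecotype_effects `list(amplitude_ratio, onset_delay,
#'   offset_delay)`: multiplicative gain ratio (wing-reduced /
#'   full-winged), additive latency delay (s) and additive decay-time
#'   increase (s) applied to wing-reduced antennae.
#' @param noise_sd additive Gaussian noise SD (mV).
#' @param drift_amplitude,drift_timescale slow sinusoidal baseline
#'   drift: amplitude (mV) and period (s).
#' @param artifact_probability probability that a recording contains one
#'   step-like baseline shift.
#' @param artifact_magnitude absolute step size (mV) of the baseline
#'   shift artifact.
#' @param n_antennae number of antennae per ecotype in a cohort.
#' @param between_antenna_sd SD of per-antenna log2 gain around the
#'   ecotype mean (the variance the random intercept must absorb).
#' @param log2_residual_sd residual SD on the log2 scale used by
#'   [simulate_metrics_table()].
#' @param isi inter-stimulus interval (s) between main-series onsets.
#' @param rng_seed integer master seed; identical seed and config give
#'   bit-identical output.
#' @param preset `"stonefly"` (slow, default) or `"honeybee"` (fast
#'   antenna and fast odorant dynamics).
#' @return an object of class `eag_config`.
#' @export
#' @examples
#' cfg <- eag_config(n_antennae = 2, rng_seed = 42)
#' fast <- eag_config(preset = "honeybee")
eag_config <- function(sampling_rate = 1000,
                       odorant_kinetics = list(
                         "2-heptanone" = list(rise = 0.080, decay = 0.250),
                         "1-octanol"   = list(rise = 0.100, decay = 0.350),
                         "2-butanone"  = list(rise = 0.065, decay = 0.200)),
                       antenna_kinetics = list(latency = 0.02, rise = 0.35,
                                               decay = 0.55, gain = 2.0),
                       ecotype_effects = list(amplitude_ratio = 2^-0.5,
                                              onset_delay = 0.05,
                                              offset_delay = 0.05),
                       noise_sd = 0.1,
                       drift_amplitude = 0.2,
                       drift_timescale = 60,
                       artifact_probability = 0,
                       artifact_magnitude = 2.0,
                       n_antennae = 10,
                       between_antenna_sd = 0.4,
                       log2_residual_sd = 0.25,
                       isi = 5,
                       rng_seed = 1,
                       preset = c("stonefly", "honeybee")) {
  preset <- match.arg(preset)
  if (preset == "honeybee") {
    if (missing(antenna_kinetics))
      antenna_kinetics <- list(latency = 0.005, rise = 0.008, decay = 0.010,
                               gain = 2.0)
    if (missing(odorant_kinetics))
      odorant_kinetics <- list(
        "2-heptanone" = list(rise = 0.010, decay = 0.020),
        "1-octanol"   = list(rise = 0.010, decay = 0.020),
        "2-butanone"  = list(rise = 0.010, decay = 0.020))
  }
  cfg <- structure(list(
    sampling_rate = sampling_rate,
    odorant_kinetics = odorant_kinetics,
    antenna_kinetics = antenna_kinetics,
    ecotype_effects = ecotype_effects,
    noise_sd = noise_sd,
    drift_amplitude = drift_amplitude,
    drift_timescale = drift_timescale,
    artifact_probability = artifact_probability,
    artifact_magnitude = artifact_magnitude,
    n_antennae = n_antennae,
    between_antenna_sd = between_antenna_sd,
    log2_residual_sd = log2_residual_sd,
    isi = isi,
    rng_seed = as.integer(rng_seed),
    preset = preset), class = "eag_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk_pos <- function(x, what) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
      stop_config(what, " must be strictly positive")
  }
  chk_pos(cfg$sampling_rate, "sampling_rate")
  chk_pos(cfg$isi, "isi")
  if (cfg$noise_sd < 0) stop_config("noise_sd must be >= 0")
  for (od in names(cfg$odorant_kinetics)) {
    k <- cfg$odorant_kinetics[[od]]
    chk_pos(c(k$rise, k$decay), paste0("odorant_kinetics[", od, "]"))
  }
  ak <- cfg$antenna_kinetics
  chk_pos(c(ak$rise, ak$decay), "antenna rise/decay")
  if (ak$latency < 0) stop_config("antenna latency must be >= 0")
  ee <- cfg$ecotype_effects
  if (ee$amplitude_ratio < 0) stop_config("amplitude_ratio must be >= 0")
  if (cfg$artifact_probability < 0 || cfg$artifact_probability > 1)
    stop_config("artifact_probability must be in [0, 1]")
  if (cfg$n_antennae < 1) stop_config("n_antennae must be >= 1")
  if (cfg$between_antenna_sd < 0) stop_config("between_antenna_sd must be >= 0")
  invisible(cfg)
}

#' Build the olfactory stimulation protocol
#'
#' For each odorant, each pulse duration (15, 30, 150, 300 ms valve open
#' time) is presented ten times at a 5-s inter-stimulus interval. Ten
#' seconds after the last 300-ms stimulus of an odorant, a 10-Hz pulse
#' train follows: the valve opens for 50 ms at 100-ms period, 30
#' openings spanning 3 s. Five seconds after the train, the next
#' odorant begins. The experiment ends with a final control block of
#' ten 300-ms stimuli of the first odorant, used to test whether the
#' antenna is still responsive.
#'
#' @param config an [eag_config()] object.
#' @param odorants ordered character vector of odorant labels; each must
#'   have kinetics in `config$odorant_kinetics`.
#' @param durations_ms main-series valve open times (ms).
#' @param t_start onset (s) of the first stimulus.
#' @return data.frame of class `eag_protocol` with columns `onset_s`,
#'   `valve_open_s`, `odorant`, `block` (main / train / control) and
#'   `repeat_index` (1..10 for main and control, 1..30 for train).
#' @export
#' @examples
#' p <- build_protocol(eag_config(), "2-heptanone")
#' nrow(p)  # 40 main + 30 train + 10 control = 80
build_protocol <- function(config, odorants,
                           durations_ms = c(15, 30, 150, 300),
                           t_start = 5) {
  if (length(odorants) == 0) stop_config("odorant list must be non-empty")
  validate_config(config)
  if (any(durations_ms <= 0)) stop_config("pulse durations must be positive")
  missing_k <- setdiff(odorants, names(config$odorant_kinetics))
  if (length(missing_k))
    stop_config("no kinetics configured for odorant(s): ",
                paste(missing_k, collapse = ", "))
  isi <- config$isi
  rows <- list()
  t <- t_start
  for (od in odorants) {
    for (d in durations_ms) {
      rows[[length(rows) + 1L]] <- data.frame(
        onset_s = t + (0:9) * isi, valve_open_s = d / 1000,
        odorant = od, block = "main", repeat_index = 1:10)
      t <- t + 10 * isi
    }
    last_main <- t - isi                 # onset of the 10th longest pulse
    train_start <- last_main + 10        # 10 s after the last 300 ms stimulus
    rows[[length(rows) + 1L]] <- data.frame(
      onset_s = train_start + (0:29) * 0.1, valve_open_s = 0.05,
      odorant = od, block = "train", repeat_index = 1:30)
    t <- train_start + 3 + 5             # next odorant 5 s after the train
  }
  rows[[length(rows) + 1L]] <- data.frame(
    onset_s = t + (0:9) * isi, valve_open_s = 0.3,
    odorant = odorants[1], block = "control", repeat_index = 1:10)
  proto <- do.call(rbind, rows)
  rownames(proto) <- NULL
  class(proto) <- c("eag_protocol", "data.frame")
  proto
}

#' Odorant concentration trace for a protocol
#'
#' Passes the 0/1 valve state through a first-order low-pass: the
#' concentration relaxes toward 1 with time constant `kinetics$rise`
#' while the valve is open, and toward 0 with `kinetics$decay` after it
#' closes. Computed exactly, segment by segment, from the closed-form
#' step response, so peaks obey `1 - exp(-open_time / rise)`.
#'
#' @param protocol an `eag_protocol` (or any data.frame with `onset_s`,
#'   `valve_open_s` and `odorant` columns).
#' @param kinetics `list(rise, decay)` time constants in seconds.
#' @param sampling_rate samples per second.
#' @param odorant optional label: only that odorant's valve events drive
#'   the trace. Default uses all events.
#' @param t_end trace end time (s); defaults to 5 s after the last
#'   event onset.
#' @return numeric concentration vector in `[0, 1]`, sampled at
#'   `0, 1/fs, 2/fs, ...`.
#' @export
concentration_trace <- function(protocol, kinetics, sampling_rate,
                                odorant = NULL, t_end = NULL) {
  if (kinetics$rise <= 0 || kinetics$decay <= 0)
    stop_config("odorant time constants must be strictly positive")
  ev <- protocol
  if (!is.null(odorant)) ev <- ev[ev$odorant == odorant, , drop = FALSE]
  if (is.null(t_end)) t_end <- max(protocol$onset_s) + 5
  n <- as.integer(round(t_end * sampling_rate))
  conc <- numeric(n)
  if (nrow(ev) == 0) return(conc)
  tt <- (seq_len(n) - 1) / sampling_rate
  ## breakpoints: valve transition times, in order
  opens <- ev$onset_s
  closes <- ev$onset_s + ev$valve_open_s
  bp <- sort(unique(c(0, opens, closes, t_end)))
  state <- 0
  for (s in seq_len(length(bp) - 1L)) {
    a <- bp[s]; b <- bp[s + 1L]
    open <- any(opens <= a + .time_eps & closes >= b - .time_eps)
    target <- if (open) 1 else 0
    tau <- if (open) kinetics$rise else kinetics$decay
    idx <- which(tt >= a - .time_eps & tt < b - .time_eps)
    if (length(idx))
      conc[idx] <- target + (state - target) * exp(-(tt[idx] - a) / tau)
    state <- target + (state - target) * exp(-(b - a) / tau)
  }
  conc
}

## asymmetric first-order relaxation of the antennal response toward the
## drive: fast(ish) rise while the drive exceeds the state, slower decay
## back toward baseline afterwards.
antenna_filter <- function(drive, sampling_rate, rise, decay) {
  ar <- exp(-1 / (sampling_rate * rise))
  ad <- exp(-1 / (sampling_rate * decay))
  n <- length(drive)
  out <- numeric(n)
  r <- 0
  for (i in seq_len(n)) {
    d <- drive[i]
    a <- if (d > r) ar else ad
    r <- d + (r - d) * a
    out[i] <- r
  }
  out
}

#' Generate one synthetic EAG recording
#'
#' The voltage is a linear first-order cascade: per-odorant valve states
#' are low-passed into concentration traces ([concentration_trace()]),
#' delayed by the transduction latency, passed through an asymmetric
#' first-order filter (rise constant while concentration drives the
#' response up, decay constant on the way back), and scaled by the
#' antenna gain. Gaussian noise, slow sinusoidal drift and (with
#' configured probability) a single step-like baseline-shift artifact
#' are added. Positive deflections are excitatory, matching the EAG
#' sign convention used throughout the package.
#'
#' Wing-reduced antennae have their gain multiplied by
#' `ecotype_effects$amplitude_ratio`, their latency increased by
#' `onset_delay` and their decay constant increased by `offset_delay`,
#' unless the `antenna` list supplies explicit values.
#'
#' @param config an [eag_config()].
#' @param protocol an `eag_protocol` from [build_protocol()].
#' @param antenna list with `antenna_id`, `ecotype` (`"full-winged"`,
#'   `"wing-reduced"` or `"reference"`), optional `population`, and
#'   optional overrides `gain`, `latency`, `rise`, `decay`, `seed`.
#' @return an [eag_recording()] object.
#' @export
generate_recording <- function(config, protocol, antenna) {
  validate_config(config)
  stopifnot(!is.null(antenna$antenna_id), !is.null(antenna$ecotype))
  fs <- config$sampling_rate
  wr <- identical(antenna$ecotype, "wing-reduced")
  ak <- config$antenna_kinetics
  ee <- config$ecotype_effects
  gain <- antenna$gain %||% (ak$gain * if (wr) ee$amplitude_ratio else 1)
  latency <- antenna$latency %||% (ak$latency + if (wr) ee$onset_delay else 0)
  rise <- antenna$rise %||% ak$rise
  decay <- antenna$decay %||% (ak$decay + if (wr) ee$offset_delay else 0)
  t_end <- max(protocol$onset_s) + 5
  n <- as.integer(round(t_end * fs))

  drive <- numeric(n)
  for (od in unique(protocol$odorant)) {
    conc <- concentration_trace(protocol, config$odorant_kinetics[[od]],
                                fs, odorant = od, t_end = t_end)
    drive <- drive + conc
  }
  lag <- as.integer(round(latency * fs))
  if (lag > 0) drive <- c(numeric(lag), drive[seq_len(n - lag)])
  v <- gain * antenna_filter(drive, fs, rise, decay)

  seed <- antenna$seed %||%
    derive_seed(config$rng_seed, paste0("recording/", antenna$antenna_id))
  v <- with_seed(seed, {
    ## fixed draw order so that zeroing one component leaves the others
    ## unchanged under the same seed
    noise <- rnorm(n, 0, config$noise_sd)
    phase <- runif(1, 0, 2 * pi)
    u_art <- runif(1)
    t_art <- runif(1, 0.05, 0.95)
    s_art <- sample(c(-1, 1), 1)
    tt <- (seq_len(n) - 1) / fs
    drift <- config$drift_amplitude *
      sin(2 * pi * tt / config$drift_timescale + phase)
    out <- v + noise + drift
    if (u_art < config$artifact_probability) {
      i0 <- as.integer(floor(t_art * n)) + 1L
      out[i0:n] <- out[i0:n] + s_art * config$artifact_magnitude
    }
    out
  })

  eag_recording(antenna_id = antenna$antenna_id,
                ecotype = antenna$ecotype,
                population = antenna$population %||% "synthetic",
                sampling_rate = fs, t0 = 0, voltage = v,
                events = as.data.frame(protocol))
}

#' Generate a paired cohort of recordings with ground truth
#'
#' Simulates `n_antennae` full-winged and `n_antennae` wing-reduced
#' antennae under a common protocol, mirroring the paired recording
#' design in which antennae of both ecotypes are measured
#' simultaneously. Per-antenna gains are drawn around the ecotype mean
#' on the log2 scale with SD `between_antenna_sd`; this between-antenna
#' variance is what the random intercept of the strength model must
#' absorb.
#'
#' @param config an [eag_config()].
#' @param odorants odorant labels passed to [build_protocol()].
#' @param population population label recorded in metadata.
#' @return list with `recordings` (list of [eag_recording()]),
#'   `ground_truth` (data.frame of true per-antenna gains and kinetics,
#'   plus the cohort-level true log2 amplitude ratio and timing deltas)
#'   and `protocol`.
#' @export
generate_cohort <- function(config, odorants = names(config$odorant_kinetics),
                            population = "synthetic") {
  validate_config(config)
  if (config$n_antennae < 1) stop_config("n_antennae must be >= 1")
  protocol <- build_protocol(config, odorants)
  n <- config$n_antennae
  ak <- config$antenna_kinetics
  ee <- config$ecotype_effects
  ids <- c(sprintf("fw%02d", seq_len(n)), sprintf("wr%02d", seq_len(n)))
  ecotypes <- rep(c("full-winged", "wing-reduced"), each = n)
  log2_gain <- with_seed(derive_seed(config$rng_seed, "cohort"), {
    mu <- log2(ak$gain) + ifelse(ecotypes == "wing-reduced",
                                 log2(ee$amplitude_ratio), 0)
    rnorm(2 * n, mu, config$between_antenna_sd)
  })
  gt <- data.frame(
    antenna_id = ids, ecotype = ecotypes, population = population,
    true_gain_mV = 2^log2_gain,
    true_latency_s = ak$latency +
      ifelse(ecotypes == "wing-reduced", ee$onset_delay, 0),
    true_rise_s = ak$rise,
    true_decay_s = ak$decay +
      ifelse(ecotypes == "wing-reduced", ee$offset_delay, 0),
    true_log2_ratio = log2(ee$amplitude_ratio),
    true_onset_delay_s = ee$onset_delay,
    true_offset_delay_s = ee$offset_delay)
  recordings <- lapply(seq_along(ids), function(i) {
    generate_recording(config, protocol, list(
      antenna_id = ids[i], ecotype = ecotypes[i], population = population,
      gain = gt$true_gain_mV[i], latency = gt$true_latency_s[i],
      rise = gt$true_rise_s[i], decay = gt$true_decay_s[i]))
  })
  names(recordings) <- ids
  list(recordings = recordings, ground_truth = gt, protocol = protocol)
}

#' Simulate a response-metrics table directly (no signal synthesis)
#'
#' Draws per-antenna response strengths and timings from the same
#' generative parameters as [generate_cohort()] but at the level of the
#' metrics table, skipping signal synthesis and extraction. Used for
#' calibration and parameter-recovery studies of the inference layer,
#' where hundreds of replicate cohorts are needed: strength is
#' `gain_i * (1 - exp(-duration / rise_odorant))` with lognormal
#' residual noise; onset and offset are lognormal around ecotype
#' medians shifted by the configured additive delays.
#'
#' @param config an [eag_config()].
#' @param odorant odorant label (sets the concentration rise constant).
#' @param population population label.
#' @param onset_base,offset_base full-winged median onset/offset (s).
#' @param seed RNG seed; defaults to a seed derived from
#'   `config$rng_seed`.
#' @return data.frame with one row per antenna x pulse duration:
#'   `antenna_id`, `ecotype`, `population`, `odorant`,
#'   `pulse_duration_ms`, `strength_mV`, `onset_s`, `offset_s`.
#' @export
simulate_metrics_table <- function(config, odorant = "2-heptanone",
                                   population = "synthetic",
                                   onset_base = 0.15, offset_base = 1.5,
                                   seed = NULL) {
  validate_config(config)
  seed <- seed %||% derive_seed(config$rng_seed, "metrics-table")
  n <- config$n_antennae
  durations <- c(15, 30, 150, 300)
  kin <- config$odorant_kinetics[[odorant]]
  if (is.null(kin)) stop_config("no kinetics configured for ", odorant)
  ak <- config$antenna_kinetics
  ee <- config$ecotype_effects
  ids <- c(sprintf("fw%02d", seq_len(n)), sprintf("wr%02d", seq_len(n)))
  ecotypes <- rep(c("full-winged", "wing-reduced"), each = n)
  with_seed(seed, {
    mu <- log2(ak$gain) + ifelse(ecotypes == "wing-reduced",
                                 log2(ee$amplitude_ratio), 0)
    log2_gain <- rnorm(2 * n, mu, config$between_antenna_sd)
    tab <- expand.grid(antenna_id = ids, pulse_duration_ms = durations,
                       stringsAsFactors = FALSE)
    tab <- tab[order(match(tab$antenna_id, ids), tab$pulse_duration_ms), ]
    rownames(tab) <- NULL
    m <- nrow(tab)
    i <- match(tab$antenna_id, ids)
    wr <- ecotypes[i] == "wing-reduced"
    peak <- 1 - exp(-(tab$pulse_duration_ms / 1000) / kin$rise)
    sdl <- config$log2_residual_sd
    tab$ecotype <- ecotypes[i]
    tab$population <- population
    tab$odorant <- odorant
    tab$strength_mV <- 2^(log2_gain[i] + log2(peak) + rnorm(m, 0, sdl))
    tab$onset_s <- (onset_base + ifelse(wr, ee$onset_delay, 0)) *
      2^rnorm(m, 0, sdl)
    tab$offset_s <- (offset_base + ifelse(wr, ee$offset_delay, 0)) *
      2^rnorm(m, 0, sdl)
    tab[, c("antenna_id", "ecotype", "population", "odorant",
            "pulse_duration_ms", "strength_mV", "onset_s", "offset_s")]
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
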