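## stats: strength and timing models with flat-prior posterior
## simulation and ecotype contrasts.

#' Log2 transform of response strength
#'
#' An offset of 0.01 is added before the log2 transform to keep weakly
#' negative mean responses in the domain; the inverse transform
#' subtracts the offset again.
#'
#' @param strength_mV numeric; must exceed -0.01.
#' @return value on the modelling (log2) scale.
#' @export
#' @examples
#' transform_strength(0.99)  # log2(1) = 0
transform_strength <- function(strength_mV) {
  if (any(strength_mV <= -0.01, na.rm = TRUE))
    stop("strength <= -0.01 mV cannot be log2 transformed")
  log2(strength_mV + 0.01)
}

#' @rdname transform_strength
#' @param y value on the modelling scale.
#' @export
inv_transform_strength <- function(y) 2^y - 0.01

.as_model_frame <- function(table, odorant = NULL, population = NULL) {
  d <- as.data.frame(table)
  if (!is.null(odorant)) d <- d[d$odorant == odorant, , drop = FALSE]
  if (!is.null(population)) d <- d[d$population == population, , drop = FALSE]
  d$ecotype <- factor(d$ecotype, levels = c("full-winged", "wing-reduced"))
  d$duration <- factor(d$pulse_duration_ms,
                       levels = sort(unique(d$pulse_duration_ms)))
  d
}

#' Fit the response-strength mixed model
#'
#' Linear mixed model for log2-transformed response strength with
#' ecotype, pulse duration (categorical, reference level 15 ms) and
#' their interaction as fixed effects, and a random intercept per
#' antenna to account for repeated measurements of the same antenna.
#' Fitted by REML via \pkg{lme4}. One model per odorant and
#' population, matching the analysis design.
#'
#' Rows with strength at or below -0.01 mV (outside the transform
#' domain) are dropped and counted in the result.
#'
#' @param table metrics table: one row per antenna x odorant x
#'   pulse duration with columns `antenna_id`, `ecotype`, `population`,
#'   `odorant`, `pulse_duration_ms`, `strength_mV`.
#' @param odorant,population optional filters applied before fitting.
#' @return object of class `eag_fit` with elements `type = "lmer"`,
#'   `model`, `beta` (fixed effects), `V` (their covariance), `sigma`
#'   (residual SD), `ranef_sd` (random-intercept SD), `n`, `n_dropped`,
#'   `response = "strength"`, `offset = 0.01`.
#' @export
fit_strength_model <- function(table, odorant = NULL, population = NULL) {
  d <- .as_model_frame(table, odorant, population)
  bad <- !is.finite(d$strength_mV) | d$strength_mV <= -0.01
  n_dropped <- sum(bad)
  d <- d[!bad, , drop = FALSE]
  if (length(unique(d$ecotype[!is.na(d$ecotype)])) < 2)
    stop("strength model needs both ecotypes")
  per_eco <- table(unique(d[, c("antenna_id", "ecotype")])$ecotype)
  if (length(per_eco) < 2 || any(per_eco < 2))
    stop("strength model needs >= 2 antennae per ecotype")
  if (nlevels(droplevels(d$duration)) < 2)
    stop("strength model needs >= 2 pulse-duration levels")
  d$duration <- droplevels(d$duration)
  d$y <- transform_strength(d$strength_mV)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ ecotype * duration + (1 | antenna_id), data = d,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(type = "lmer", model = fit,
                 beta = lme4::fixef(fit),
                 V = as.matrix(vcov(fit)),
                 sigma = stats::sigma(fit),
                 ranef_sd = vc$sdcor[vc$grp == "antenna_id"][1],
                 df = NA_real_,
                 n = nrow(d), n_dropped = n_dropped,
                 response = "strength", offset = 0.01,
                 durations = levels(d$duration)),
            class = "eag_fit")
}

#' Fit a response-timing linear model
#'
#' Simple linear model for the log2-transformed response onset or
#' offset time of 300-ms pulses, with ecotype as the only explanatory
#' variable. Times are strictly positive, so no offset is added before
#' the transform. Rows with invalid (missing or non-positive) timing
#' are excluded and counted.
#'
#' @param table metrics table (see [fit_strength_model()]) with
#'   `onset_s` and `offset_s` columns.
#' @param which `"onset"` or `"offset"`.
#' @param odorant,population optional filters.
#' @param duration_ms pulse duration modelled (default 300).
#' @return object of class `eag_fit` with `type = "lm"`, coefficient
#'   estimates, unscaled covariance, residual SD and degrees of
#'   freedom.
#' @export
fit_timing_model <- function(table, which = c("onset", "offset"),
                             odorant = NULL, population = NULL,
                             duration_ms = 300) {
  which <- match.arg(which)
  d <- .as_model_frame(table, odorant, population)
  d <- d[d$pulse_duration_ms == duration_ms, , drop = FALSE]
  timing <- d[[paste0(which, "_s")]]
  bad <- !is.finite(timing) | timing <= 0
  n_dropped <- sum(bad)
  d <- d[!bad, , drop = FALSE]
  timing <- timing[!bad]
  per_eco <- table(unique(d[, c("antenna_id", "ecotype")])$ecotype)
  if (length(per_eco) < 2 || any(per_eco < 2))
    stop("timing model needs >= 2 antennae per ecotype")
  d$y <- log2(timing)
  fit <- lm(y ~ ecotype, data = d)
  ## degenerate noiseless inputs are legitimate in tests; summary()'s
  ## "essentially perfect fit" warning is not actionable here
  s <- suppressWarnings(summary(fit))
  structure(list(type = "lm", model = fit,
                 beta = coef(fit),
                 V = s$cov.unscaled * s$sigma^2,
                 cov_unscaled = s$cov.unscaled,
                 sigma = s$sigma,
                 ranef_sd = NA_real_,
                 df = fit$df.residual,
                 n = nrow(d), n_dropped = n_dropped,
                 response = which, offset = 0,
                 durations = as.character(duration_ms)),
            class = "eag_fit")
}

#' @export
print.eag_fit <- function(x, ...) {
  cat(sprintf("<eag_fit> %s model for %s (n = %d, dropped %d)\n",
              x$type, x$response, x$n, x$n_dropped))
  print(x$beta)
  invisible(x)
}

## symmetric matrix square root tolerant of (near-)singular covariance
.mat_sqrt <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate flat-prior posterior draws for a fitted model
#'
#' For the linear (timing) model, draws follow the standard
#' flat-prior normal-inverse-chi-squared posterior: the residual
#' variance is drawn from its scaled inverse-chi-squared posterior
#' (residual degrees of freedom), then the coefficient vector from a
#' multivariate normal centred at the estimates with covariance scaled
#' by the drawn variance. For the mixed (strength) model, variance
#' components are held at their REML estimates and fixed effects are
#' drawn from a multivariate normal with the fitted coefficient
#' covariance — the flat-prior approximation used by `arm::sim`-style
#' workflows, documented as an approximation.
#'
#' @param fit an `eag_fit`.
#' @param n_sim number of draws (default 10000).
#' @param seed integer seed; the same seed gives identical draws.
#' @return object of class `eag_posterior`: list with `draws`
#'   (`n_sim` x p matrix, named columns), `sigma` (residual-SD draws),
#'   `type`, `response`, `offset`, `durations`.
#' @export
simulate_posterior <- function(fit, n_sim = 10000, seed = NULL) {
  stopifnot(inherits(fit, "eag_fit"))
  if (n_sim < 1) stop_config("n_sim must be >= 1")
  p <- length(fit$beta)
  with_seed(seed, {
    Z <- matrix(rnorm(n_sim * p), n_sim, p)
    if (fit$type == "lm") {
      sigma_draws <- fit$sigma * sqrt(fit$df / rchisq(n_sim, fit$df))
      draws <- Z %*% .mat_sqrt(fit$cov_unscaled)
      draws <- draws * sigma_draws   # recycled column-wise
    } else {
      sigma_draws <- rep(fit$sigma, n_sim)
      draws <- Z %*% .mat_sqrt(fit$V)
    }
    draws <- sweep(draws, 2, fit$beta, `+`)
    colnames(draws) <- names(fit$beta)
    structure(list(draws = draws, sigma = sigma_draws, type = fit$type,
                   response = fit$response, offset = fit$offset,
                   durations = fit$durations),
              class = "eag_posterior")
  })
}

.stars <- function(certainty) {
  ifelse(certainty > 0.99, "**", ifelse(certainty > 0.95, "*", ""))
}

#' Summarize an ecotype contrast from posterior draws
#'
#' Computes the wing-reduced minus full-winged contrast per draw (at
#' one pulse-duration level for the strength model), the 95% credible
#' interval (2.5% and 97.5% quantiles), the certainty — the larger of
#' the proportions of draws in which one ecotype exceeds the other, so
#' it is direction-agnostic — and the asterisk label (`"*"` above 0.95,
#' `"**"` above 0.99). Group-level fitted values are back-transformed
#' to the original scale for plotting (subtracting the 0.01 offset for
#' strength).
#'
#' @param posterior an `eag_posterior` from [simulate_posterior()].
#' @param duration_ms duration level of the contrast (strength model);
#'   ignored for timing models.
#' @return one-row data.frame: `response`, `duration_ms`, `delta_log2`
#'   (posterior-mean contrast on the modelling scale), `lo_log2`,
#'   `hi_log2`, `certainty`, `direction` (which ecotype is larger),
#'   `stars`, and back-transformed group means and 95% CI limits
#'   `fw_mean`, `fw_lo`, `fw_hi`, `wr_mean`, `wr_lo`, `wr_hi`.
#' @export
summarize_comparison <- function(posterior, duration_ms = NULL) {
  stopifnot(inherits(posterior, "eag_posterior"))
  draws <- posterior$draws
  cn <- colnames(draws)
  eco <- "ecotypewing-reduced"
  if (!eco %in% cn) stop("no ecotype coefficient in posterior draws")
  delta <- draws[, eco]
  fw <- draws[, "(Intercept)"]
  dur <- NA_real_
  if (posterior$type == "lmer") {
    if (is.null(duration_ms)) duration_ms <- posterior$durations[1]
    duration_ms <- as.character(duration_ms)
    if (!duration_ms %in% posterior$durations)
      stop("duration ", duration_ms, " not in the fitted model")
    dur_col <- paste0("duration", duration_ms)
    int_col <- paste0(eco, ":", dur_col)
    if (dur_col %in% cn) fw <- fw + draws[, dur_col]
    if (int_col %in% cn) delta <- delta + draws[, int_col]
    dur <- as.numeric(duration_ms)
  } else {
    dur <- as.numeric(posterior$durations[1])
  }
  wr <- fw + delta
  p_wr_gt_fw <- mean(delta > 0)
  certainty <- max(p_wr_gt_fw, 1 - p_wr_gt_fw)
  back <- function(x) 2^x - posterior$offset
  qs <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  dq <- qs(delta); fq <- qs(fw); wq <- qs(wr)
  data.frame(response = posterior$response,
             duration_ms = dur,
             delta_log2 = mean(delta),
             lo_log2 = dq[1], hi_log2 = dq[2],
             certainty = certainty,
             direction = if (p_wr_gt_fw >= 0.5) "wing-reduced > full-winged"
                         else "full-winged > wing-reduced",
             stars = .stars(certainty),
             fw_mean = back(mean(fw)), fw_lo = back(fq[1]),
             fw_hi = back(fq[2]),
             wr_mean = back(mean(wr)), wr_lo = back(wq[1]),
             wr_hi = back(wq[2]))
}
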