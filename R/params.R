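#' Reference parameters for the fly activity generator
#'
#' Constructs the parameter set of the generative model of fly locomotor
#' activity. The model is a discrete-time two-process-style state machine:
#' sleep onset is driven by a bimodal circadian propensity (siesta plus a
#' larger night peak) multiplied by homeostatic sleep pressure, and each onset
#' draws a heavy-tailed (lognormal) inactivity-bout duration whose scale also
#' grows with pressure, so accrued sleep debt discharges preferentially into
#' long (>= 25 min) bouts. Mechanical stimulation can force the next epoch
#' active and leaves a decaying "hyperactivity" elevation of active speed that
#' also suppresses sleep onset - the sleep-independent masking effect of
#' mechanical deprivation.
#'
#' The defaults are the frozen reference calibration used throughout: they
#' produce a bimodal standard-sleep profile with roughly twice as much
#' long-bout (>= 25 min) sleep at night as during the day, and a mean of
#' 12-14 inactivity-triggered rotations per fly per 24 h under the 1320-s
#' (22-min) trigger.
#'
#' @param circ_base baseline sleep-onset weight, all ZT.
#' @param siesta_height,siesta_center,siesta_width Gaussian daytime (siesta)
#'   component of the circadian propensity (height, ZT hours, hours).
#' @param night_height,night_center,night_width Gaussian nighttime component.
#' @param onset_base per-epoch sleep-onset probability at unit circadian
#'   weight, zero pressure.
#' @param pressure_gain homeostatic pressure accrued per awake epoch.
#' @param pressure_decay pressure discharged per asleep epoch.
#' @param pressure_init pressure at the start of the trace (the reference
#'   value is the model's approximate day-to-day equilibrium).
#' @param pressure_onset_coef multiplier linking pressure to onset
#'   probability: onset scales with `1 + pressure_onset_coef * P`.
#' @param pressure_bout_coef multiplier linking pressure to bout duration:
#'   the lognormal scale is multiplied by `1 + pressure_bout_coef * P`.
#' @param bout_meanlog_day,bout_meanlog_night,bout_sdlog lognormal parameters
#'   of the inactivity-bout duration distribution (in epochs), day (ZT0-12)
#'   and night (ZT12-24) modes.
#' @param active_meanlog,active_sdlog lognormal parameters of the active-speed
#'   excess above the 1 mm/s immobility boundary; active speeds are
#'   `1 + lognormal * modulation`, so their support is strictly above 1 mm/s.
#' @param act_morning_height,act_evening_height,act_peak_width crepuscular
#'   modulation of active speed: Gaussian morning (ZT0.5) and evening (ZT11.5)
#'   activity peaks on a baseline of 1.
#' @param rest_max upper bound of the uniform resting-speed distribution
#'   (must be < 1 mm/s; immobility is handled strictly by construction).
#' @param arousal_prob probability that a stimulus forces the next epoch
#'   active.
#' @param hyperactivity_gain post-stimulus increment of the hyperactivity
#'   elevation (dimensionless multiplier on active speed).
#' @param hyperactivity_max saturation cap of the elevation.
#' @param hyperactivity_halflife_h exponential decay half-life of the
#'   elevation, hours.
#' @param seed default master seed used when a generator call does not supply
#'   one.
#' @return an object of class `fly_params` (a validated named list).
#' @seealso [generate_trace()], [generate_cohort()], [run_experiment()]
#' @export
fly_params <- function(circ_base = 0.12,
                       siesta_height = 0.55,
                       siesta_center = 7,
                       siesta_width = 2,
                       night_height = 1.0,
                       night_center = 18,
                       night_width = 3.5,
                       onset_base = 0.012,
                       pressure_gain = 2.2e-4,
                       pressure_decay = 2.9e-4,
                       pressure_init = 0.55,
                       pressure_onset_coef = 0.5,
                       pressure_bout_coef = 1.5,
                       bout_meanlog_day = log(46),
                       bout_meanlog_night = log(78),
                       bout_sdlog = 0.95,
                       active_meanlog = log(2.0),
                       active_sdlog = 0.5,
                       act_morning_height = 0.6,
                       act_evening_height = 1.1,
                       act_peak_width = 1.5,
                       rest_max = 0.8,
                       arousal_prob = 1.0,
                       hyperactivity_gain = 0.05,
                       hyperactivity_max = 1.5,
                       hyperactivity_halflife_h = 16,
                       seed = 1L) {
  p <- list(
    circ_base = circ_base, siesta_height = siesta_height,
    siesta_center = siesta_center, siesta_width = siesta_width,
    night_height = night_height, night_center = night_center,
    night_width = night_width, onset_base = onset_base,
    pressure_gain = pressure_gain, pressure_decay = pressure_decay,
    pressure_init = pressure_init,
    pressure_onset_coef = pressure_onset_coef,
    pressure_bout_coef = pressure_bout_coef,
    bout_meanlog_day = bout_meanlog_day,
    bout_meanlog_night = bout_meanlog_night, bout_sdlog = bout_sdlog,
    active_meanlog = active_meanlog, active_sdlog = active_sdlog,
    act_morning_height = act_morning_height,
    act_evening_height = act_evening_height,
    act_peak_width = act_peak_width, rest_max = rest_max,
    arousal_prob = arousal_prob, hyperactivity_gain = hyperactivity_gain,
    hyperactivity_max = hyperactivity_max,
    hyperactivity_halflife_h = hyperactivity_halflife_h,
    seed = as.integer(seed))
  validate_fly_params(p)
  structure(p, class = "fly_params")
}

validate_fly_params <- function(p) {
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all generator parameters must be numeric")
  if (any(!is.finite(unlist(p)))) stop("generator parameters must be finite")
  if (p$onset_base < 0 || p$onset_base > 1)
    stop("onset_base must be a probability in [0, 1]")
  if (p$arousal_prob < 0 || p$arousal_prob > 1)
    stop("arousal_prob must be a probability in [0, 1]")
  if (p$rest_max <= 0 || p$rest_max >= 1)
    stop("rest_max must lie strictly inside (0, 1) mm/s: resting speeds ",
         "must fall strictly below the 1 mm/s immobility boundary")
  if (p$bout_sdlog < 0 || p$active_sdlog < 0)
    stop("lognormal spreads must be non-negative")
  if (p$pressure_gain < 0 || p$pressure_decay < 0 || p$pressure_init < 0)
    stop("pressure parameters must be non-negative")
  if (p$circ_base < 0 || p$siesta_height < 0 || p$night_height < 0)
    stop("circadian propensity components must be non-negative")
  if (p$hyperactivity_gain < 0 || p$hyperactivity_max < 0 ||
      p$hyperactivity_halflife_h <= 0)
    stop("hyperactivity parameters must be non-negative (half-life > 0)")
  invisible(p)
}

#' @export
print.fly_params <- function(x, ...) {
  cat("<fly_params> generator reference parameters\n")
  cat(sprintf("  circadian: base %.2f, siesta %.2f @ZT%g, night %.2f @ZT%g\n",
              x$circ_base, x$siesta_height, x$siesta_center,
              x$night_height, x$night_center))
  cat(sprintf("  onset_base %.3f; pressure gain/decay %.1e/%.1e (init %.2f)\n",
              x$onset_base, x$pressure_gain, x$pressure_decay,
              x$pressure_init))
  cat(sprintf("  bouts: lognormal meanlog %.2f (day) / %.2f (night), sdlog %.2f\n",
              x$bout_meanlog_day, x$bout_meanlog_night, x$bout_sdlog))
  cat(sprintf("  arousal_prob %.2f; hyperactivity gain %.3f (cap %.2f, t1/2 %g h)\n",
              x$arousal_prob, x$hyperactivity_gain, x$hyperactivity_max,
              x$hyperactivity_halflife_h))
  invisible(x)
}

# internal: circadian sleep-onset weight at ZT hours (vectorized)
circadian_propensity <- function(zt, p) {
  p$circ_base +
    p$siesta_height * exp(-0.5 * ((zt - p$siesta_center) / p$siesta_width)^2) +
    p$night_height * exp(-0.5 * ((zt - p$night_center) / p$night_width)^2)
}

# internal: crepuscular modulation of active speed (morning/evening peaks);
# peaks wrap around the ZT0/ZT24 boundary
activity_modulation <- function(zt, p) {
  dm <- pmin(abs(zt - 0.5), 24 - abs(zt - 0.5))
  de <- pmin(abs(zt - 11.5), 24 - abs(zt - 11.5))
  1 + p$act_morning_height * exp(-0.5 * (dm / p$act_peak_width)^2) +
    p$act_evening_height * exp(-0.5 * (de / p$act_peak_width)^2)
}
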