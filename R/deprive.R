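# Virtual sleep-deprivation engines.
#
# Two regimes, mirroring the two lab modalities:
#  * fixed-interval "vortexer" shaking: one 2-s shake at a uniformly random
#    offset within every consecutive interval (20/120/220 s), delivered
#    monitor-wide to every fly at the same times;
#  * closed-loop inactivity-triggered tube rotation: a fly's tube is rotated
#    each time it accumulates the threshold amount of continuous immobility
#    (220 s to forbid standard 5-min sleep, 1320 s to forbid only >= 25 min
#    long-bout sleep), with a yoked partner receiving identical, time-locked
#    rotations regardless of its own state.

#' Deprivation engine configuration
#'
#' @param mode `"fixed_interval"` (monitor-wide shaking) or
#'   `"inactivity_triggered"` (closed-loop rotation).
#' @param interval_s shake interval in seconds (fixed-interval mode; the
#'   reference protocols use 20, 120 or 220 s).
#' @param shake_s shake duration in seconds (fixed-interval mode).
#' @param trigger_threshold_s inactivity threshold T in seconds
#'   (inactivity-triggered mode; 220 s or 1320 s in the reference protocols).
#'   Must be a positive multiple of the 10-s epoch length.
#' @param stimulus_duration_s rotation duration, seconds (nominal; a stimulus
#'   marks the whole 10-s epoch it lands in).
#' @param window_start_h,window_h deprivation window: start in hours since
#'   trace start, and duration in hours (6, 12 or 24 in the reference
#'   protocols).
#' @param arousal_prob optional override of the generator's arousal
#'   probability during this run.
#' @return an object of class `engine_config`.
#' @export
engine_config <- function(mode = c("inactivity_triggered", "fixed_interval"),
                          interval_s = 220, shake_s = 2,
                          trigger_threshold_s = 220,
                          stimulus_duration_s = 1,
                          window_start_h = 24, window_h = 24,
                          arousal_prob = NULL) {
  mode <- match.arg(mode)
  if (mode == "inactivity_triggered") {
    if (trigger_threshold_s <= 0 || trigger_threshold_s %% EPOCH_S != 0)
      stop("trigger_threshold_s must be a positive multiple of the ",
           EPOCH_S, "-s epoch length")
  } else {
    if (interval_s < shake_s)
      stop("interval_s must be at least shake_s")
  }
  if (!is.null(arousal_prob) &&
      (arousal_prob < 0 || arousal_prob > 1))
    stop("arousal_prob must be in [0, 1]")
  stopifnot(window_start_h >= 0, window_h > 0)
  structure(list(mode = mode, interval_s = interval_s, shake_s = shake_s,
                 trigger_threshold_s = trigger_threshold_s,
                 stimulus_duration_s = stimulus_duration_s,
                 window_start_h = window_start_h, window_h = window_h,
                 arousal_prob = arousal_prob),
            class = "engine_config")
}

#' @export
print.engine_config <- function(x, ...) {
  if (x$mode == "inactivity_triggered")
    cat(sprintf("<engine_config> inactivity-triggered, T = %g s, window %g-%g h\n",
                x$trigger_threshold_s, x$window_start_h,
                x$window_start_h + x$window_h))
  else
    cat(sprintf("<engine_config> fixed-interval, %g-s shake every %g s, window %g-%g h\n",
                x$shake_s, x$interval_s, x$window_start_h,
                x$window_start_h + x$window_h))
  invisible(x)
}

# internal: assemble a stimulus-log data.frame
stim_log <- function(fly_id, epochs, mode, source) {
  data.frame(fly_id = rep(as.character(fly_id), length(epochs)),
             epoch = as.integer(epochs),
             zt_seconds = (as.integer(epochs) - 1L) %% EPOCHS_PER_DAY * EPOCH_S,
             mode = rep(mode, length(epochs)),
             trigger_source = rep(source, length(epochs)),
             stringsAsFactors = FALSE)
}

#' Run a closed-loop, yoked inactivity-triggered deprivation experiment
#'
#' Simulates every fly in the design. Focal flies are tracked by the virtual
#' engine: each time a focal fly accumulates `trigger_threshold_s` of
#' continuous immobility inside the deprivation window, a rotation is logged
#' and (with the arousal probability) the next epoch is forced active. The
#' yoked partner's stimulator is bound to the focal fly's tracker: it
#' receives rotations at exactly the focal fly's trigger epochs, regardless
#' of its own state. Unperturbed flies receive no stimulation. The engine is
#' coupled to the generative model, so stimulation alters all subsequent
#' behaviour (state, pressure, hyperactivity).
#'
#' @param design a [paired_design()].
#' @param params a [fly_params()] object.
#' @param n_days number of days to simulate (the window must fit inside).
#' @param cfg an [engine_config()] with mode `"inactivity_triggered"`.
#' @param seed master seed (per-fly substreams are derived from it).
#' @return an object of class `deprivation_run`: list with `cohort`
#'   (a `fly_cohort`), `logs` (stimulus-log data.frame) and `cfg`.
#' @export
run_inactivity_triggered <- function(design, params = fly_params(),
                                     n_days = 2,
                                     cfg = engine_config("inactivity_triggered"),
                                     seed = params$seed) {
  stopifnot(inherits(design, "paired_design"),
            inherits(cfg, "engine_config"))
  if (cfg$mode != "inactivity_triggered")
    stop("cfg$mode must be 'inactivity_triggered'")
  win <- hour_window(cfg$window_start_h, cfg$window_h)
  check_window(win, n_days * EPOCHS_PER_DAY)
  traces <- list()
  logs <- list()
  for (i in seq_len(nrow(design$pairs))) {
    fid <- design$pairs$focal_id[i]
    yid <- design$pairs$yoked_id[i]
    fsim <- simulate_fly(params, n_days, substream_seed(seed, fid),
                         stimulus = list(mode = "inactivity",
                                         threshold_s = cfg$trigger_threshold_s,
                                         window = win,
                                         arousal_prob = cfg$arousal_prob))
    ysim <- simulate_fly(params, n_days, substream_seed(seed, yid),
                         stimulus = list(mode = "imposed",
                                         epochs = fsim$events,
                                         arousal_prob = cfg$arousal_prob))
    traces[[fid]] <- fly_trace(fsim$values, fid, "focal")
    traces[[yid]] <- fly_trace(ysim$values, yid, "yoked")
    logs[[fid]] <- stim_log(fid, fsim$events, cfg$mode, "self")
    logs[[yid]] <- stim_log(yid, ysim$events, cfg$mode, "paired_focal")
  }
  for (uid in design$unperturbed_ids) {
    usim <- simulate_fly(params, n_days, substream_seed(seed, uid))
    traces[[uid]] <- fly_trace(usim$values, uid, "unperturbed")
    logs[[uid]] <- stim_log(uid, integer(0), cfg$mode, "self")
  }
  structure(list(cohort = structure(list(traces = traces, design = design),
                                    class = "fly_cohort"),
                 logs = do.call(rbind, unname(logs)), cfg = cfg),
            class = "deprivation_run")
}

#' Run a fixed-interval (vortexer-style) deprivation experiment
#'
#' One shake lands at a uniformly random offset within every complete
#' interval of the deprivation window; all treated flies in the monitor share
#' the same shake times (`trigger_source = "monitor_wide"`). Flies listed as
#' unperturbed receive no stimulation.
#'
#' @param fly_ids identifiers of the treated (shaken) flies.
#' @param params a [fly_params()] object.
#' @param n_days number of days to simulate.
#' @param cfg an [engine_config()] with mode `"fixed_interval"`.
#' @param seed master seed; shake times use a dedicated `"monitor"`
#'   substream, fly behaviour uses per-id substreams.
#' @param unperturbed_ids identifiers of unstimulated control flies.
#' @return an object of class `deprivation_run` (see
#'   [run_inactivity_triggered()]); its cohort's design has no pairs.
#' @export
run_fixed_interval <- function(fly_ids, params = fly_params(), n_days = 2,
                               cfg = engine_config("fixed_interval"),
                               seed = params$seed,
                               unperturbed_ids = character()) {
  stopifnot(inherits(cfg, "engine_config"))
  if (cfg$mode != "fixed_interval") stop("cfg$mode must be 'fixed_interval'")
  n <- n_days * EPOCHS_PER_DAY
  win <- hour_window(cfg$window_start_h, cfg$window_h)
  check_window(win, n)
  window_s <- cfg$window_h * 3600
  n_shakes <- floor(window_s / cfg$interval_s)
  set.seed(substream_seed(seed, "monitor"))
  offsets <- stats::runif(n_shakes, 0, cfg$interval_s - cfg$shake_s)
  shake_t <- (cfg$window_start_h * 3600) +
    (seq_len(n_shakes) - 1) * cfg$interval_s + offsets
  shake_epochs <- as.integer(shake_t %/% EPOCH_S) + 1L

  ids <- c(fly_ids, unperturbed_ids)
  if (anyDuplicated(ids)) stop("duplicate fly ids")
  traces <- list()
  logs <- list()
  for (id in fly_ids) {
    sim <- simulate_fly(params, n_days, substream_seed(seed, id),
                        stimulus = list(mode = "imposed",
                                        epochs = shake_epochs,
                                        arousal_prob = cfg$arousal_prob))
    traces[[id]] <- fly_trace(sim$values, id, "focal")
    logs[[id]] <- stim_log(id, shake_epochs, cfg$mode, "monitor_wide")
  }
  for (id in unperturbed_ids) {
    sim <- simulate_fly(params, n_days, substream_seed(seed, id))
    traces[[id]] <- fly_trace(sim$values, id, "unperturbed")
    logs[[id]] <- stim_log(id, integer(0), cfg$mode, "monitor_wide")
  }
  design <- paired_design(0, focal_ids = character(),
                          yoked_ids = character(),
                          unperturbed_ids = unperturbed_ids)
  structure(list(cohort = structure(list(traces = traces, design = design),
                                    class = "fly_cohort"),
                 logs = do.call(rbind, unname(logs)), cfg = cfg),
            class = "deprivation_run")
}

#' @export
print.deprivation_run <- function(x, ...) {
  cat("<deprivation_run>\n")
  print(x$cfg)
  print(x$cohort)
  cat(sprintf("  %d stimulus events logged\n",
              if (is.null(x$logs)) 0L else nrow(x$logs)))
  invisible(x)
}

#' Verify the yoked stimulus binding
#'
#' Regression guard for the yoking contract: every pair's focal and yoked
#' stimulus logs must be identical element-wise, and unperturbed flies must
#' have empty logs. An empty design passes vacuously.
#'
#' @param logs stimulus-log data.frame (from a `deprivation_run`).
#' @param design the [paired_design()] the logs came from.
#' @return an object of class `yoking_report`: list with logical `pass`,
#'   character `mismatched_pairs`, and character `stimulated_unperturbed`.
#' @export
verify_yoking <- function(logs, design) {
  stopifnot(inherits(design, "paired_design"))
  ev <- function(id) sort(logs$epoch[logs$fly_id == id])
  bad_pairs <- character()
  for (i in seq_len(nrow(design$pairs))) {
    fe <- ev(design$pairs$focal_id[i])
    ye <- ev(design$pairs$yoked_id[i])
    if (!identical(fe, ye))
      bad_pairs <- c(bad_pairs, sprintf("%s/%s", design$pairs$focal_id[i],
                                        design$pairs$yoked_id[i]))
  }
  bad_unpert <- design$unperturbed_ids[
    vapply(design$unperturbed_ids, function(id) length(ev(id)) > 0,
           logical(1))]
  structure(list(pass = length(bad_pairs) == 0 && length(bad_unpert) == 0,
                 mismatched_pairs = bad_pairs,
                 stimulated_unperturbed = as.character(bad_unpert)),
            class = "yoking_report")
}

#' @export
print.yoking_report <- function(x, ...) {
  if (x$pass) cat("<yoking_report> PASS: all pairs matched, controls clean\n")
  else {
    cat("<yoking_report> FAIL\n")
    if (length(x$mismatched_pairs))
      cat("  mismatched pairs:", paste(x$mismatched_pairs, collapse = ", "),
          "\n")
    if (length(x$stimulated_unperturbed))
      cat("  stimulated unperturbed flies:",
          paste(x$stimulated_unperturbed, collapse = ", "), "\n")
  }
  invisible(x)
}
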