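# Generative model of fly locomotor activity on the 10-s epoch grid, plus
# the coupling point for the virtual deprivation engines: the engine acts on
# the simulated fly *while it runs* (stimuli alter subsequent behaviour),
# not as a post-hoc edit of a finished trace.

#' Construct a velocity trace object
#'
#' @param values numeric vector of per-epoch maximal speeds (mm/s, >= 0);
#'   length must be a whole number of 8640-epoch days.
#' @param fly_id identifier.
#' @param condition one of `"focal"`, `"yoked"`, `"unperturbed"`.
#' @return an object of class `fly_trace`.
#' @export
fly_trace <- function(values, fly_id, condition = "unperturbed") {
  stopifnot(is.numeric(values), all(is.finite(values)), all(values >= 0))
  if (length(values) %% EPOCHS_PER_DAY != 0)
    stop("trace length must be a whole number of ", EPOCHS_PER_DAY,
         "-epoch days")
  condition <- match.arg(condition, c("focal", "yoked", "unperturbed"))
  structure(list(fly_id = as.character(fly_id), condition = condition,
                 values = as.numeric(values), epoch_s = EPOCH_S,
                 n_days = length(values) %/% EPOCHS_PER_DAY),
            class = "fly_trace")
}

#' @export
print.fly_trace <- function(x, ...) {
  cat(sprintf("<fly_trace> %s (%s): %d days, %d epochs, %.1f%% immobile\n",
              x$fly_id, x$condition, x$n_days, length(x$values),
              100 * mean(x$values < 1)))
  invisible(x)
}

# internal: deterministic per-fly substream seed below 2^31, derived from the
# master seed and the fly id, so cohort membership or ordering changes never
# perturb an individual fly's trace.
substream_seed <- function(master_seed, id) {
  m <- 2147483647  # 2^31 - 1
  s <- as.numeric(master_seed) %% m
  for (ch in utf8ToInt(as.character(id))) s <- (s * 31 + ch) %% m
  as.integer(s + 1)
}

# internal: single-fly state-machine simulation.
#
# stimulus: NULL, or a list with
#   mode        "inactivity" (closed loop, self-triggered) or "imposed"
#   threshold_s inactivity trigger threshold (mode "inactivity")
#   window      half-open epoch window c(start, end) the engine is armed in
#   epochs      imposed stimulus epochs (mode "imposed")
#   arousal_prob override of params$arousal_prob
#
# Trigger semantics: consecutive immobile epochs are counted inside the
# window; the trigger fires in the epoch where accumulated immobile time
# first reaches threshold_s, then the timer re-arms, regardless of whether
# arousal succeeds. With probability arousal_prob the next epoch is forced
# active and the hyperactivity elevation is incremented (capped).
simulate_fly <- function(params, n_days, seed, stimulus = NULL) {
  n <- n_days * EPOCHS_PER_DAY
  set.seed(as.integer(seed))
  u_on   <- stats::runif(n)
  z_bout <- stats::rnorm(n)
  v_rest <- stats::runif(n, 0, params$rest_max)
  exc    <- exp(stats::rnorm(n, params$active_meanlog, params$active_sdlog))
  u_ar   <- stats::runif(n)

  zt <- zt_of_epoch(seq_len(n))
  w  <- circadian_propensity(zt, params)
  am <- activity_modulation(zt, params)
  mu <- ifelse(zt < 12, params$bout_meanlog_day, params$bout_meanlog_night)
  hdec <- 2^(-EPOCH_S / (3600 * params$hyperactivity_halflife_h))

  mode <- 0L
  thr <- 0L; win0 <- 0L; win1 <- 0L
  imposed <- NULL
  ap <- params$arousal_prob
  if (!is.null(stimulus)) {
    mode <- switch(stimulus$mode, inactivity = 1L, imposed = 2L,
                   stop("unknown stimulus mode: ", stimulus$mode))
    if (!is.null(stimulus$arousal_prob)) ap <- stimulus$arousal_prob
    if (mode == 1L) {
      if (stimulus$threshold_s %% EPOCH_S != 0)
        stop("trigger threshold must be a multiple of the ", EPOCH_S,
             "-s epoch length")
      thr <- as.integer(stimulus$threshold_s / EPOCH_S)
      win <- check_window(stimulus$window, n)
      win0 <- win[1]; win1 <- win[2]
    } else {
      imposed <- logical(n)
      ev <- as.integer(stimulus$epochs)
      if (any(ev < 1 | ev > n)) stop("imposed stimulus epochs outside trace")
      imposed[ev] <- TRUE
    }
  }

  v <- numeric(n)
  events <- integer(0)
  asleep <- FALSE; rem <- 0L; forced <- FALSE
  P <- params$pressure_init; h <- 0; imm <- 0L
  g <- params$pressure_gain; d <- params$pressure_decay
  aP <- params$pressure_onset_coef; bP <- params$pressure_bout_coef
  p0 <- params$onset_base; sdl <- params$bout_sdlog
  hg <- params$hyperactivity_gain; hmax <- params$hyperactivity_max

  for (t in seq_len(n)) {
    fo <- forced  # a forced epoch is genuinely active: no onset check in it
    if (fo) { asleep <- FALSE; rem <- 0L; forced <- FALSE }
    if (!asleep && !fo) {
      p_on <- p0 * w[t] * (1 + aP * P) / (1 + h)
      if (p_on > 0.5) p_on <- 0.5
      if (u_on[t] < p_on) {
        asleep <- TRUE
        rem <- max(1L, as.integer(round(exp(mu[t] + log1p(bP * P) +
                                              sdl * z_bout[t]))))
      }
    }
    if (asleep) {
      v[t] <- v_rest[t]
      P <- P - d; if (P < 0) P <- 0
      rem <- rem - 1L
      if (rem <= 0L) asleep <- FALSE
      if (mode == 1L && t >= win0 && t < win1) {
        imm <- imm + 1L
        if (imm >= thr) {
          events[length(events) + 1L] <- t
          imm <- 0L
          if (u_ar[t] < ap) {
            forced <- TRUE
            h <- h + hg; if (h > hmax) h <- hmax
          }
        }
      }
    } else {
      v[t] <- 1 + exc[t] * am[t] * (1 + h)
      P <- P + g
      if (mode == 1L) imm <- 0L
    }
    if (mode == 2L && imposed[t]) {
      events[length(events) + 1L] <- t
      if (u_ar[t] < ap) {
        forced <- TRUE
        h <- h + hg; if (h > hmax) h <- hmax
      }
    }
    h <- h * hdec
  }
  list(values = v, events = events)
}

#' Generate a synthetic fly velocity trace
#'
#' Simulates an unperturbed fly under the two-process-style generative model
#' (see [fly_params()]). Identical `(params, n_days, seed)` yield
#' bit-identical traces.
#'
#' @param params a [fly_params()] object.
#' @param n_days number of 24-h days to simulate (>= 1).
#' @param seed RNG seed for this trace; defaults to `params$seed`.
#' @param fly_id identifier stored in the trace.
#' @return a [fly_trace()] with condition `"unperturbed"`.
#' @export
generate_trace <- function(params = fly_params(), n_days = 1,
                           seed = params$seed, fly_id = "fly_01") {
  stopifnot(n_days >= 1)
  validate_fly_params(params)
  sim <- simulate_fly(params, n_days, seed)
  fly_trace(sim$values, fly_id, "unperturbed")
}

#' Construct a paired (focal/yoked) experimental design
#'
#' @param n_pairs number of focal/yoked pairs.
#' @param n_unperturbed number of unperturbed control flies.
#' @param focal_ids,yoked_ids,unperturbed_ids optional explicit identifiers;
#'   defaults are `focal_01 ...`, `yoked_01 ...`, `ctrl_01 ...`.
#' @return an object of class `paired_design` with elements `pairs`
#'   (data.frame of `focal_id`, `yoked_id`) and `unperturbed_ids`.
#' @export
paired_design <- function(n_pairs, n_unperturbed = 0,
                          focal_ids = NULL, yoked_ids = NULL,
                          unperturbed_ids = NULL) {
  if (is.null(focal_ids)) focal_ids <- sprintf("focal_%02d", seq_len(n_pairs))
  if (is.null(yoked_ids)) yoked_ids <- sprintf("yoked_%02d", seq_len(n_pairs))
  if (is.null(unperturbed_ids) && n_unperturbed > 0)
    unperturbed_ids <- sprintf("ctrl_%02d", seq_len(n_unperturbed))
  if (length(focal_ids) != length(yoked_ids))
    stop("focal and yoked id lists must have equal length")
  ids <- c(focal_ids, yoked_ids, unperturbed_ids)
  if (anyDuplicated(ids))
    stop("duplicate fly ids in design: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(pairs = data.frame(focal_id = as.character(focal_ids),
                                    yoked_id = as.character(yoked_ids),
                                    stringsAsFactors = FALSE),
                 unperturbed_ids = as.character(unperturbed_ids %||% character())),
            class = "paired_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.paired_design <- function(x, ...) {
  cat(sprintf("<paired_design> %d focal/yoked pairs, %d unperturbed\n",
              nrow(x$pairs), length(x$unperturbed_ids)))
  invisible(x)
}

# internal: all ids of a design, with their condition labels
design_conditions <- function(design) {
  c(stats::setNames(rep("focal", nrow(design$pairs)), design$pairs$focal_id),
    stats::setNames(rep("yoked", nrow(design$pairs)), design$pairs$yoked_id),
    stats::setNames(rep("unperturbed", length(design$unperturbed_ids)),
                    design$unperturbed_ids))
}

#' Generate an unperturbed cohort of traces
#'
#' One trace per design id. Each fly runs on an independently seeded RNG
#' substream derived from the master seed and its id, so reordering or
#' resizing the cohort leaves individual traces unchanged. Condition labels
#' come from the design; no stimulation is applied (use
#' [run_inactivity_triggered()] / [run_fixed_interval()] for that).
#'
#' @param design a [paired_design()].
#' @param params a [fly_params()] object.
#' @param n_days number of days to simulate.
#' @param seed master seed.
#' @return an object of class `fly_cohort`: list with `traces` (named list of
#'   [fly_trace()]) and `design`.
#' @export
generate_cohort <- function(design, params = fly_params(), n_days = 1,
                            seed = params$seed) {
  stopifnot(inherits(design, "paired_design"))
  conds <- design_conditions(design)
  traces <- lapply(names(conds), function(id) {
    sim <- simulate_fly(params, n_days, substream_seed(seed, id))
    fly_trace(sim$values, id, conds[[id]])
  })
  names(traces) <- names(conds)
  structure(list(traces = traces, design = design), class = "fly_cohort")
}

#' @export
print.fly_cohort <- function(x, ...) {
  conds <- vapply(x$traces, `[[`, "", "condition")
  cat(sprintf("<fly_cohort> %d flies (%s), %d days\n", length(x$traces),
              paste(sprintf("%d %s", as.vector(table(conds)),
                            names(table(conds))), collapse = ", "),
              if (length(x$traces)) x$traces[[1]]$n_days else 0))
  invisible(x)
}

#' Convert a velocity trace to DAM-style beam-crossing counts
#'
#' Emulates a TriKinetics Drosophila Activity Monitor recording: per-bin
#' integer beam-crossing counts. Bins in which the fly is immobile throughout
#' emit zero counts; bins containing activity emit at least one crossing,
#' with counts Poisson-distributed with mean `lambda` times the bin's mean
#' speed.
#'
#' @param trace a [fly_trace()].
#' @param bin_s bin width in seconds; must be a multiple of the 10-s epoch
#'   length and divide 86400. DAM hardware records every 20 s.
#' @param lambda expected beam crossings per bin per unit mean speed (mm/s).
#' @param seed RNG seed for the Poisson emission.
#' @return integer vector of counts, one per bin.
#' @export
to_dam_counts <- function(trace, bin_s = 20, lambda = 2, seed = 1L) {
  stopifnot(inherits(trace, "fly_trace"))
  if (bin_s %% EPOCH_S != 0)
    stop("bin_s must be a multiple of the ", EPOCH_S, "-s epoch length")
  if (86400 %% bin_s != 0) stop("bin_s must divide 86400")
  k <- bin_s %/% EPOCH_S
  n_bins <- length(trace$values) %/% k
  m <- matrix(trace$values[seq_len(n_bins * k)], nrow = k)
  mean_speed <- colMeans(m)
  any_mobile <- colSums(m >= 1) > 0
  set.seed(as.integer(seed))
  counts <- stats::rpois(n_bins, lambda * mean_speed)
  counts[any_mobile & counts < 1] <- 1L
  counts[!any_mobile] <- 0L
  as.integer(counts)
}
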