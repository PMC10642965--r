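# End-to-end experiment runner: simulate -> deprive -> score -> rebound
# (-> maldi), chained from one master seed, with a reproducibility manifest.

EXPERIMENT_DESIGNS <- c("yoked-220", "yoked-1320", "vortex-grid")

#' Run a built-in experimental design end to end
#'
#' Built-in designs (all 12:12 LD, one baseline day, a 24-h deprivation
#' window starting at lights-on of day 2, then recovery days):
#' \describe{
#'   \item{`yoked-220`}{closed-loop 220-s inactivity trigger with yoked
#'     controls - forbids standard (>= 5 min) sleep in focal flies.}
#'   \item{`yoked-1320`}{closed-loop 1320-s (22-min) trigger with yoked
#'     controls - forbids only long-bout (>= 25 min) sleep.}
#'   \item{`vortex-grid`}{monitor-wide fixed-interval shaking at 20, 120 and
#'     220 s with frequency-matched unperturbed monitors; produces the
#'     treatment x frequency sleep-gain table for [interaction_anova()].}
#' }
#'
#' @param design one of the built-in design names.
#' @param seed master seed; all randomness flows from it through named
#'   per-fly substreams.
#' @param n_pairs focal/yoked pairs (yoked designs).
#' @param n_unperturbed unperturbed controls (yoked designs).
#' @param n_per_monitor flies per monitor (vortex design).
#' @param n_post recovery days after the deprivation day.
#' @param params generator parameters; defaults to the frozen reference
#'   calibration [fly_params()].
#' @param sweep if `TRUE` (yoked designs), also compute the 1-30 min
#'   [criterion_sweep()] surface.
#' @param maldi if `TRUE`, also generate a planted [generate_peak_table()]
#'   fixture and screen it with [maldi_screen()].
#' @param out_dir optional directory: write traces, logs, summaries,
#'   rebound/sweep tables and the manifest as CSV/text files.
#' @return list of class `experiment_result`; components depend on the
#'   design (`run`, `yoking`, `summaries`, `rebound`, `sweep`, `gain_table`,
#'   `anova`, `maldi`, `manifest`).
#' @export
run_experiment <- function(design = EXPERIMENT_DESIGNS, seed = 1L,
                           n_pairs = 20, n_unperturbed = 15,
                           n_per_monitor = 16, n_post = 3,
                           params = fly_params(), sweep = FALSE,
                           maldi = FALSE, out_dir = NULL) {
  if (!design[1] %in% EXPERIMENT_DESIGNS)
    stop("unknown design '", design[1], "'; built-ins: ",
         paste(EXPERIMENT_DESIGNS, collapse = ", "))
  design <- match.arg(design)
  n_days <- 2L + n_post
  out <- list(design = design, seed = as.integer(seed), params = params)

  if (design %in% c("yoked-220", "yoked-1320")) {
    thr <- if (design == "yoked-220") 220 else 1320
    cfg <- engine_config("inactivity_triggered", trigger_threshold_s = thr,
                         window_start_h = 24, window_h = 24)
    des <- paired_design(n_pairs, n_unperturbed)
    run <- run_inactivity_triggered(des, params, n_days, cfg, seed)
    out$run <- run
    out$yoking <- verify_yoking(run$logs, des)
    out$summaries <- do.call(rbind, c(
      lapply(run$cohort$traces, sleep_summary, criterion_s = 300),
      make.row.names = FALSE))
    out$rebound <- rebound_table(run, criterion_s = 300, n_post = n_post)
    out$rebound_long <- rebound_table(run, criterion_s = 1500,
                                      n_post = n_post)
    if (sweep) out$sweep <- criterion_sweep(run, n_post = n_post)
  } else {
    freqs <- c(20, 120, 220)
    runs <- list()
    gain_rows <- list()
    for (f in freqs) {
      cfg <- engine_config("fixed_interval", interval_s = f,
                           window_start_h = 24, window_h = 24)
      ids <- sprintf("vx%ds_%02d", f, seq_len(n_per_monitor))
      ctrl <- sprintf("un%ds_%02d", f, seq_len(n_per_monitor))
      r <- run_fixed_interval(ids, params, n_days, cfg, seed,
                              unperturbed_ids = ctrl)
      runs[[as.character(f)]] <- r
      cds <- cohort_day_sleep(r$cohort)
      for (id in c(ids, ctrl)) {
        gain_rows[[id]] <- data.frame(
          fly_id = id,
          treatment = if (id %in% ids) "disturbed" else "unperturbed",
          frequency = paste0(f, "s"),
          gain = cds$sleep(id, 3, 300) - cds$sleep(id, 1, 300))
      }
    }
    out$runs <- runs
    out$gain_table <- do.call(rbind, unname(gain_rows))
    out$anova <- interaction_anova(out$gain_table)
  }

  if (maldi) {
    fix <- maldi_params(seed = substream_seed(seed, "maldi"))
    out$maldi_fixture <- generate_peak_table(fix)
    out$maldi <- maldi_screen(out$maldi_fixture$table, "yoked")
  }

  if (!is.null(out_dir)) out$manifest <- write_experiment(out, out_dir)
  class(out) <- "experiment_result"
  out
}

# internal: persist stage outputs and build the digest manifest
write_experiment <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  save_csv <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  if (!is.null(out$run)) {
    p <- file.path(out_dir, "traces.csv")
    write_traces(out$run$cohort, p); paths[["traces.csv"]] <- p
    p <- file.path(out_dir, "stimulus_log.csv")
    write_stimulus_log(out$run$logs, p); paths[["stimulus_log.csv"]] <- p
  }
  if (!is.null(out$summaries)) save_csv(out$summaries, "sleep_summaries.csv")
  if (!is.null(out$rebound)) save_csv(out$rebound, "rebound_standard.csv")
  if (!is.null(out$rebound_long)) save_csv(out$rebound_long,
                                           "rebound_long_bout.csv")
  if (!is.null(out$sweep)) {
    p <- file.path(out_dir, "sweep_surface.csv")
    utils::write.csv(data.frame(criterion_min = rownames(out$sweep),
                                unclass(out$sweep), check.names = FALSE),
                     p, row.names = FALSE)
    paths[["sweep_surface.csv"]] <- p
  }
  if (!is.null(out$gain_table)) save_csv(out$gain_table, "gain_table.csv")
  if (!is.null(out$maldi)) {
    save_csv(out$maldi$classification, "maldi_classification.csv")
  }
  cfg_path <- file.path(out_dir, "params.conf")
  write_config(out$params, cfg_path); paths[["params.conf"]] <- cfg_path
  manifest <- data.frame(file = names(paths),
                         md5 = unname(tools::md5sum(unlist(paths))),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(cbind(design = out$design, seed = out$seed, manifest),
                   manifest_path, row.names = FALSE)
  manifest
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> design %s, seed %d\n", x$design, x$seed))
  if (!is.null(x$yoking)) print(x$yoking)
  if (!is.null(x$anova)) {
    cat("  treatment x frequency ANOVA:\n")
    print(x$anova, row.names = FALSE)
  }
  if (!is.null(x$maldi)) print(x$maldi)
  invisible(x)
}
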