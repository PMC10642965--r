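# Plain-text interchange formats: long-format trace CSV, stimulus-log CSV,
# and a flat key = value config file carrying the generator parameters and
# master seed.

#' Write / read velocity traces as long-format CSV
#'
#' Columns: `fly_id`, `condition`, `epoch_index`, `zt_seconds`,
#' `max_velocity_mm_s`.
#'
#' @param x a `fly_cohort`, a list of [fly_trace()] objects, or a single
#'   trace.
#' @param path CSV path.
#' @return `path` invisibly (writer); a named list of [fly_trace()] objects
#'   (reader).
#' @export
write_traces <- function(x, path) {
  traces <- if (inherits(x, "fly_cohort")) x$traces
            else if (inherits(x, "fly_trace")) list(x)
            else x
  dfs <- lapply(traces, function(tr) {
    n <- length(tr$values)
    data.frame(fly_id = tr$fly_id, condition = tr$condition,
               epoch_index = seq_len(n),
               zt_seconds = ((seq_len(n) - 1L) %% EPOCHS_PER_DAY) * EPOCH_S,
               max_velocity_mm_s = tr$values)
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fly_id", "condition", "epoch_index", "max_velocity_mm_s")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$fly_id), function(d) {
    d <- d[order(d$epoch_index), ]
    fly_trace(d$max_velocity_mm_s, d$fly_id[1], d$condition[1])
  })
  out[unique(df$fly_id)]
}

#' Write / read a stimulus log as CSV
#'
#' Columns: `fly_id`, `epoch`, `zt_seconds`, `mode`, `trigger_source`.
#'
#' @param logs stimulus-log data.frame (from a `deprivation_run`).
#' @param path CSV path.
#' @export
write_stimulus_log <- function(logs, path) {
  utils::write.csv(logs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_log
#' @export
read_stimulus_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read generator parameters as a flat key = value config file
#'
#' One `key = value` line per [fly_params()] field (TOML-style scalars,
#' `#` comments allowed). The shipped reference calibration is at
#' `system.file("extdata", "reference_params.conf", package = "somnoyoke")`.
#'
#' @param params a [fly_params()] object.
#' @param path config file path.
#' @return `path` invisibly (writer); a [fly_params()] (reader).
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "fly_params"))
  lines <- c("# somnoyoke generator parameters",
             vapply(names(params), function(k)
               sprintf("%s = %.15g", k, params[[k]]), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", lines))
  if (any(lengths(kv) != 3))
    stop("malformed config line: ", lines[which(lengths(kv) != 3)[1]])
  keys <- vapply(kv, `[`, "", 2)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 3)))
  if (anyNA(vals)) stop("non-numeric config value for key: ",
                        keys[which(is.na(vals))[1]])
  do.call(fly_params, as.list(stats::setNames(vals, keys)))
}
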