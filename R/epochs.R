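# Epoch-grid conventions shared by every stage of the pipeline.
#
# Activity is recorded as the maximal velocity (mm/s) within consecutive 10-s
# epochs, 8640 epochs per 24-h day. Epochs are half-open [t, t + 10) and the
# grid is anchored to Zeitgeber time: ZT0 = lights-on, ZT12 = lights-off.

EPOCH_S <- 10
EPOCHS_PER_DAY <- 8640L

#' Zeitgeber time of epoch indices
#'
#' @param epoch 1-based epoch index (or vector of indices) into a trace that
#'   starts at ZT0 of its first day.
#' @return ZT in hours, in `[0, 24)`.
#' @export
zt_of_epoch <- function(epoch) {
  ((epoch - 1) %% EPOCHS_PER_DAY) * (EPOCH_S / 3600)
}

#' Epoch window covering one experimental day
#'
#' Windows are half-open epoch-index pairs `c(start, end)`: the window covers
#' epochs `start, ..., end - 1` (1-based).
#'
#' @param day day number, 1-based.
#' @return integer vector `c(start, end)`.
#' @export
day_window <- function(day) {
  stopifnot(day >= 1)
  c((day - 1L) * EPOCHS_PER_DAY + 1L, day * EPOCHS_PER_DAY + 1L)
}

#' Epoch window from hours since trace start
#'
#' @param start_h start of the window, hours since the beginning of the trace
#'   (the trace starts at ZT0 of day 1).
#' @param duration_h window length in hours.
#' @return integer vector `c(start, end)`, half-open.
#' @export
hour_window <- function(start_h, duration_h) {
  stopifnot(start_h >= 0, duration_h > 0)
  start <- as.integer(round(start_h * 3600 / EPOCH_S)) + 1L
  c(start, start + as.integer(round(duration_h * 3600 / EPOCH_S)))
}

# internal: validate a half-open epoch window against a trace length
check_window <- function(window, n_epochs) {
  if (is.null(window)) return(c(1L, n_epochs + 1L))
  stopifnot(length(window) == 2, window[1] >= 1, window[2] > window[1])
  if (window[2] > n_epochs + 1L)
    stop("window extends beyond the trace (", n_epochs, " epochs)")
  as.integer(window)
}
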