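# Sleep scoring: velocity -> immobility -> bouts -> sleep quantities.
#
# Conventions (strict, by construction): an epoch is immobile iff its maximal
# velocity is < 1 mm/s (strict inequality at the boundary); a bout of sleep
# is a maximal run of immobile epochs whose duration is >= the inactivity
# criterion (closed inequality), 300 s by default. Bouts spanning an
# analysis-window boundary are split at the boundary and each fragment is
# re-tested against the criterion within its window, which keeps per-day
# totals additive.

#' Immobility mask of a velocity trace
#'
#' @param trace a [fly_trace()] or a numeric velocity vector.
#' @param threshold immobility threshold in mm/s; an epoch is immobile iff
#'   its velocity is strictly below this value.
#' @return logical vector, `TRUE` = immobile.
#' @export
immobility_mask <- function(trace, threshold = 1.0) {
  v <- if (inherits(trace, "fly_trace")) trace$values else trace
  stopifnot(is.numeric(v))
  v < threshold
}

#' Detect immobility bouts
#'
#' Extracts the maximal runs of immobile epochs from a logical mask.
#'
#' @param mask logical vector (`TRUE` = immobile), non-empty.
#' @param epoch_s epoch (or bin) length in seconds underlying the mask.
#' @return a data.frame of class `bout_table` with columns `start` (1-based
#'   first epoch), `end` (exclusive), `duration_s`; attribute `epoch_s` and
#'   `n_epochs` record the grid.
#' @export
detect_bouts <- function(mask, epoch_s = EPOCH_S) {
  stopifnot(is.logical(mask), length(mask) > 0)
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = as.integer(starts[keep]),
                    end = as.integer(ends[keep] + 1L),
                    duration_s = r$lengths[keep] * epoch_s)
  attr(out, "epoch_s") <- epoch_s
  attr(out, "n_epochs") <- length(mask)
  class(out) <- c("bout_table", "data.frame")
  out
}

# internal: clip bout fragments to a half-open epoch window; returns
# durations (s) of the clipped fragments (zero-length fragments dropped)
clip_bouts <- function(bouts, window, epoch_s) {
  if (nrow(bouts) == 0) return(numeric())
  s <- pmax(bouts$start, window[1])
  e <- pmin(bouts$end, window[2])
  d <- (e - s) * epoch_s
  d[d > 0]
}

#' Total sleep under an inactivity criterion
#'
#' Sums the durations of immobility bouts at least as long as the criterion,
#' within an analysis window, in minutes. Bouts spanning the window boundary
#' are split there and the fragments re-tested against the criterion, so
#' per-day totals are additive. Monotonically non-increasing in the
#' criterion.
#'
#' @param bouts a `bout_table` from [detect_bouts()].
#' @param criterion_s inactivity criterion in seconds (standard sleep: 300;
#'   long-bout/deep sleep: 1500). Must be a positive multiple of the epoch
#'   length underlying the bouts.
#' @param window half-open epoch window `c(start, end)`, or `NULL` for the
#'   whole trace.
#' @return total sleep in minutes.
#' @export
sleep_time <- function(bouts, criterion_s = 300, window = NULL) {
  epoch_s <- attr(bouts, "epoch_s") %||% EPOCH_S
  if (criterion_s <= 0 || criterion_s %% epoch_s != 0)
    stop("criterion_s must be a positive multiple of the epoch length (",
         epoch_s, " s)")
  window <- check_window(window, attr(bouts, "n_epochs") %||% Inf)
  d <- clip_bouts(bouts, window, epoch_s)
  sum(d[d >= criterion_s]) / 60
}

#' Short ("active") sleep time
#'
#' Total time, in minutes, spent in inactivity bouts of between 1 min
#' (inclusive) and 5 min (exclusive) - the band proposed as a brief,
#' shallower sleep state below the standard criterion.
#'
#' @inheritParams sleep_time
#' @param band half-open duration band in seconds, default `[60, 300)`.
#' @export
short_sleep_time <- function(bouts, window = NULL, band = c(60, 300)) {
  epoch_s <- attr(bouts, "epoch_s") %||% EPOCH_S
  window <- check_window(window, attr(bouts, "n_epochs") %||% Inf)
  d <- clip_bouts(bouts, window, epoch_s)
  sum(d[d >= band[1] & d < band[2]]) / 60
}

#' Sleep-bout architecture
#'
#' Count and mean duration of the bouts meeting the criterion within a
#' window (boundary-split, like [sleep_time()]).
#'
#' @inheritParams sleep_time
#' @return list with `bout_count` and `mean_bout_min` (`NA` when no bout
#'   qualifies).
#' @export
bout_architecture <- function(bouts, criterion_s = 300, window = NULL) {
  epoch_s <- attr(bouts, "epoch_s") %||% EPOCH_S
  if (criterion_s <= 0 || criterion_s %% epoch_s != 0)
    stop("criterion_s must be a positive multiple of the epoch length")
  window <- check_window(window, attr(bouts, "n_epochs") %||% Inf)
  d <- clip_bouts(bouts, window, epoch_s)
  d <- d[d >= criterion_s]
  list(bout_count = length(d),
       mean_bout_min = if (length(d)) mean(d) / 60 else NA_real_)
}

# internal: collapse an epoch-level activity mask to activity bins
activity_bins <- function(mask, bin_s, epoch_s) {
  if (bin_s %% epoch_s != 0)
    stop("bin_s must be a multiple of the epoch length")
  k <- bin_s %/% epoch_s
  n_bins <- length(mask) %/% k
  if (n_bins < 2) stop("need at least 2 bins")
  active <- !mask[seq_len(n_bins * k)]
  colSums(matrix(active, nrow = k)) > 0
}

#' P(doze): conditional probability that activity is followed by inactivity
#'
#' A sleep-pressure proxy: the probability that an active time bin is
#' followed by an inactive bin. Computed on coarse activity bins (a bin is
#' active iff any of its epochs is active).
#'
#' @param mask epoch-level immobility mask (`TRUE` = immobile).
#' @param bin_s bin width in seconds (default 60).
#' @param epoch_s epoch length underlying the mask.
#' @return probability in `[0, 1]`, or `NA` (undefined) when there is no
#'   active bin with a successor.
#' @export
p_doze <- function(mask, bin_s = 60, epoch_s = EPOCH_S) {
  b <- activity_bins(mask, bin_s, epoch_s)
  a <- b[-length(b)]
  s <- b[-1]
  if (!any(a)) return(NA_real_)
  sum(a & !s) / sum(a)
}

#' P(wake): conditional probability that inactivity is followed by activity
#'
#' Symmetric counterpart of [p_doze()]: the probability that an inactive bin
#' is followed by an active bin.
#'
#' @inheritParams p_doze
#' @return probability in `[0, 1]`, or `NA` when there is no inactive bin
#'   with a successor.
#' @export
p_wake <- function(mask, bin_s = 60, epoch_s = EPOCH_S) {
  b <- activity_bins(mask, bin_s, epoch_s)
  a <- b[-length(b)]
  s <- b[-1]
  if (!any(!a)) return(NA_real_)
  sum(!a & s) / sum(!a)
}

#' Per-fly, per-window sleep summary
#'
#' @param trace a [fly_trace()].
#' @param criterion_s inactivity criterion in seconds.
#' @param window half-open epoch window, or `NULL` for the whole trace.
#' @param threshold immobility threshold, mm/s.
#' @param pdoze_bin_s bin width for the P(doze)/P(wake) metrics.
#' @return one-row data.frame: fly id, condition, window (ZT hours from
#'   trace start), criterion, total/short sleep (min), bout count, mean bout
#'   duration (min), p_doze, p_wake.
#' @export
sleep_summary <- function(trace, criterion_s = 300, window = NULL,
                          threshold = 1.0, pdoze_bin_s = 60) {
  stopifnot(inherits(trace, "fly_trace"))
  mask <- immobility_mask(trace, threshold)
  window <- check_window(window, length(mask))
  bouts <- detect_bouts(mask, trace$epoch_s)
  arch <- bout_architecture(bouts, criterion_s, window)
  sub <- mask[seq(window[1], window[2] - 1L)]
  data.frame(fly_id = trace$fly_id, condition = trace$condition,
             window_start_h = (window[1] - 1) * trace$epoch_s / 3600,
             window_end_h = (window[2] - 1) * trace$epoch_s / 3600,
             criterion_s = criterion_s,
             total_sleep_min = sleep_time(bouts, criterion_s, window),
             short_sleep_min = short_sleep_time(bouts, window),
             bout_count = arch$bout_count,
             mean_bout_min = arch$mean_bout_min,
             p_doze = p_doze(sub, pdoze_bin_s, trace$epoch_s),
             p_wake = p_wake(sub, pdoze_bin_s, trace$epoch_s),
             stringsAsFactors = FALSE)
}

#' Score beam-crossing counts as sleep bouts
#'
#' DAM-modality scoring: a bin is immobile iff its count is zero (no
#' debouncing), and bouts are the maximal runs of immobile bins.
#'
#' @param counts non-negative integer counts per bin.
#' @param bin_s bin width in seconds (DAM hardware: 20 s).
#' @return a `bout_table` (see [detect_bouts()]) on the bin grid.
#' @export
dam_sleep <- function(counts, bin_s = 20) {
  if (any(counts < 0)) stop("negative counts in DAM series")
  detect_bouts(counts == 0, epoch_s = bin_s)
}
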