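# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain scans and enumerations.

# run-length scan: maximal immobile runs from a logical mask
oracle_bouts <- function(mask, epoch_s = 10) {
  starts <- ends <- integer(0)
  in_run <- FALSE
  for (i in seq_along(mask)) {
    if (mask[i] && !in_run) { starts <- c(starts, i); in_run <- TRUE }
    if (!mask[i] && in_run) { ends <- c(ends, i); in_run <- FALSE }
  }
  if (in_run) ends <- c(ends, length(mask) + 1L)
  data.frame(start = starts, end = ends,
             duration_s = (ends - starts) * epoch_s)
}

# filter-and-sum sleep time (minutes) over whole-trace bouts
oracle_sleep_time <- function(durations_s, criterion_s) {
  sum(durations_s[durations_s >= criterion_s]) / 60
}

# inactivity-trigger timer: rescan the immobility run-length encoding; a
# trigger fires at every thr-th immobile epoch since the start of a run (or
# since the last trigger), within the window
oracle_trigger_epochs <- function(mask, thr_epochs, window) {
  events <- integer(0)
  count <- 0L
  for (t in seq_along(mask)) {
    if (t >= window[1] && t < window[2] && mask[t]) {
      count <- count + 1L
      if (count == thr_epochs) { events <- c(events, t); count <- 0L }
    } else count <- 0L
  }
  events
}

# exhaustive-enumeration Mann-Whitney U of group x (vs y): count of (i, j)
# pairs with x_i > y_j plus half-ties
oracle_mann_whitney_U <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# hand-rolled Benjamini-Hochberg step-up with monotonicity enforcement
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q[q > 1] <- 1
  out <- numeric(m)
  out[o] <- q
  out
}

# transition-counting p(doze)/p(wake) on pre-binned activity
oracle_p_doze <- function(bin_active) {
  num <- den <- 0L
  for (i in seq_len(length(bin_active) - 1)) {
    if (bin_active[i]) {
      den <- den + 1L
      if (!bin_active[i + 1]) num <- num + 1L
    }
  }
  if (den == 0) NA_real_ else num / den
}
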