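# Shared fixtures, built in code at test time.

# a trace whose only immobility is one run of `run_epochs` zero-velocity
# epochs starting at `at`, everything else at 2 mm/s
single_run_trace <- function(run_epochs, at = 1000L, n_days = 1,
                             fly_id = "fx") {
  v <- rep(2, n_days * 8640L)
  v[seq(at, length.out = run_epochs)] <- 0
  fly_trace(v, fly_id)
}

# fast generator settings for unit tests (dynamics unchanged, just handy)
test_params <- function(...) fly_params(...)

# a bout_table built directly from durations (seconds), laid out head to
# tail with 1-epoch gaps
bout_fixture <- function(durations_s, epoch_s = 10) {
  n_ep <- as.integer(durations_s / epoch_s)
  mask <- logical(0)
  for (k in n_ep) mask <- c(mask, rep(TRUE, k), FALSE)
  mask <- c(mask, rep(FALSE, 10))
  detect_bouts(mask, epoch_s)
}
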