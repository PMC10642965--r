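test_that("engine configuration is validated", {
  expect_error(engine_config("inactivity_triggered",
                             trigger_threshold_s = 225), "multiple")
  expect_error(engine_config("fixed_interval", interval_s = 1, shake_s = 2),
               "at least")
  expect_s3_class(engine_config("inactivity_triggered",
                                trigger_threshold_s = 1320), "engine_config")
})

test_that("inactivity timer fires every 22nd immobile epoch of a permanently immobile fly", {
  # propensity forced to keep the fly permanently asleep via huge bouts
  p <- test_params(onset_base = 0.5, circ_base = 10, siesta_height = 0,
                   night_height = 0, bout_meanlog_day = log(1e6),
                   bout_meanlog_night = log(1e6), bout_sdlog = 0,
                   pressure_bout_coef = 0)
  cfg <- engine_config("inactivity_triggered", trigger_threshold_s = 220,
                       window_start_h = 0, window_h = 24,
                       arousal_prob = 0)
  des <- paired_design(1, 0)
  run <- run_inactivity_triggered(des, p, 1, cfg, seed = 1)
  ev <- run$logs$epoch[run$logs$fly_id == "focal_01"]
  mask <- immobility_mask(run$cohort$traces[["focal_01"]])
  expect_gt(mean(mask), 0.99)  # asleep from the first onset onward
  want <- oracle_trigger_epochs(mask, 22L, c(1L, 8641L))
  expect_identical(as.integer(ev), want)
  # an uninterrupted 24-h immobile run carries floor(8640/22) = 392 triggers
  expect_equal(length(oracle_trigger_epochs(rep(TRUE, 8640), 22L,
                                            c(1L, 8641L))), 392L)
  # yoked partner logs are element-wise identical
  evy <- run$logs$epoch[run$logs$fly_id == "yoked_01"]
  expect_identical(ev, evy)
})

test_that("a permanently active fly triggers no events for itself or its yoked partner", {
  p <- test_params(circ_base = 0, siesta_height = 0, night_height = 0)
  cfg <- engine_config("inactivity_triggered", trigger_threshold_s = 220,
                       window_start_h = 0, window_h = 24)
  run <- run_inactivity_triggered(paired_design(1, 1), p, 1, cfg, seed = 2)
  expect_equal(nrow(run$logs), 0)
})

test_that("timer semantics match the run-length rescanning oracle on random traces", {
  # randomized immobility masks pushed through the coupled engine with
  # arousal_prob = 0 (so the engine only observes; behaviour is free-running)
  p <- test_params()
  cfg <- engine_config("inactivity_triggered", trigger_threshold_s = 220,
                       window_start_h = 0, window_h = 24, arousal_prob = 0)
  des <- paired_design(10, 0)
  run <- run_inactivity_triggered(des, p, 1, cfg, seed = 31)
  for (id in des$pairs$focal_id) {
    mask <- immobility_mask(run$cohort$traces[[id]])
    ev <- run$logs$epoch[run$logs$fly_id == id]
    expect_identical(as.integer(ev),
                     oracle_trigger_epochs(mask, 22L, c(1L, 8641L)))
  }
  # pure-mask version over many short random traces
  set.seed(77)
  for (i in 1:1000) {
    mask <- runif(300) < 0.8
    thr <- sample(c(3L, 7L, 22L), 1)
    ev <- oracle_trigger_epochs(mask, thr, c(1L, 301L))
    # the oracle itself satisfies the re-arm contract: gaps between events
    # inside one immobile run are exactly thr epochs
    if (length(ev) > 1) {
      d <- diff(ev)
      runs_between <- vapply(seq_len(length(ev) - 1), function(j)
        all(mask[ev[j]:(ev[j + 1])]), TRUE)
      expect_true(all(d[runs_between] == thr))
    }
    expect_true(all(mask[ev]))
  }
})

test_that("fixed-interval shaking delivers one shake per interval, monitor-wide", {
  p <- test_params()
  cfg <- engine_config("fixed_interval", interval_s = 220,
                       window_start_h = 0, window_h = 24)
  run <- run_fixed_interval(c("a", "b"), p, 1, cfg, seed = 5)
  ev_a <- run$logs$epoch[run$logs$fly_id == "a"]
  ev_b <- run$logs$epoch[run$logs$fly_id == "b"]
  expect_equal(length(ev_a), floor(86400 / 220))  # 392
  expect_identical(ev_a, ev_b)                    # shared shake times
  expect_true(all(run$logs$trigger_source == "monitor_wide"))
  cfg6 <- engine_config("fixed_interval", interval_s = 20,
                        window_start_h = 0, window_h = 6)
  run6 <- run_fixed_interval("a", p, 1, cfg6, seed = 5)
  expect_equal(sum(run6$logs$fly_id == "a"), 21600 / 20)  # 1080
})

test_that("yoking verification passes on engine output and names broken pairs", {
  p <- test_params()
  cfg <- engine_config("inactivity_triggered", trigger_threshold_s = 220,
                       window_start_h = 0, window_h = 24)
  des <- paired_design(3, 2)
  run <- run_inactivity_triggered(des, p, 1, cfg, seed = 12)
  rep_ok <- verify_yoking(run$logs, des)
  expect_true(rep_ok$pass)
  # delete one yoked event -> fail naming exactly that pair
  logs2 <- run$logs
  drop <- which(logs2$fly_id == "yoked_02")[1]
  expect_false(is.na(drop))
  logs2 <- logs2[-drop, ]
  rep_bad <- verify_yoking(logs2, des)
  expect_false(rep_bad$pass)
  expect_equal(rep_bad$mismatched_pairs, "focal_02/yoked_02")
  # empty design passes vacuously
  expect_true(verify_yoking(run$logs[0, ], paired_design(0, 0))$pass)
})

test_that("220-s trigger abolishes standard sleep while yoked controls keep some", {
  p <- test_params()
  cfg <- engine_config("inactivity_triggered", trigger_threshold_s = 220,
                       window_start_h = 24, window_h = 24)
  des <- paired_design(6, 6)
  run <- run_inactivity_triggered(des, p, 2, cfg, seed = 55)
  w <- day_window(2)
  sl <- function(id) sleep_time(detect_bouts(immobility_mask(
    run$cohort$traces[[id]])), 300, w)
  focal <- vapply(des$pairs$focal_id, sl, 0)
  yoked <- vapply(des$pairs$yoked_id, sl, 0)
  unpert <- vapply(des$unperturbed_ids, sl, 0)
  expect_true(all(focal == 0))
  expect_true(all(yoked > 0))
  expect_lt(mean(yoked), mean(unpert))
})
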