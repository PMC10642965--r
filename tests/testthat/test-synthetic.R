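test_that("identical seeds give bit-identical traces; different seeds differ", {
  p <- test_params()
  t1 <- generate_trace(p, 1, seed = 5)
  t2 <- generate_trace(p, 1, seed = 5)
  expect_identical(t1$values, t2$values)
  t3 <- generate_trace(p, 1, seed = 6)
  expect_false(identical(t1$values, t3$values))
  expect_equal(length(t1$values), 8640)
})

test_that("zero circadian propensity yields a sleep-free, always-mobile trace", {
  p <- test_params(circ_base = 0, siesta_height = 0, night_height = 0)
  tr <- generate_trace(p, 1, seed = 3)
  expect_true(all(tr$values >= 1))
  b <- detect_bouts(immobility_mask(tr))
  expect_equal(sleep_time(b, 300), 0)
})

test_that("invalid generator parameters are rejected", {
  expect_error(fly_params(rest_max = 1.2), "boundary")
  expect_error(fly_params(arousal_prob = 1.5), "probability")
  expect_error(fly_params(bout_sdlog = -1), "non-negative")
})

test_that("cohort traces ride per-id substreams unaffected by design membership", {
  p <- test_params()
  d1 <- paired_design(2, 1)
  co1 <- generate_cohort(d1, p, 1, seed = 99)
  expect_equal(length(co1$traces), 5)
  conds <- vapply(co1$traces, `[[`, "", "condition")
  expect_equal(sum(conds == "focal"), 2)
  expect_equal(sum(conds == "yoked"), 2)
  expect_equal(sum(conds == "unperturbed"), 1)
  expect_true(all(vapply(co1$traces, function(tr) length(tr$values), 0) ==
                    8640))
  # reorder/extend the design: each fly's trace must be unchanged
  d2 <- paired_design(3, 2,
                      focal_ids = c("focal_03", "focal_01", "focal_02"),
                      yoked_ids = c("yoked_03", "yoked_01", "yoked_02"))
  co2 <- generate_cohort(d2, p, 1, seed = 99)
  for (id in names(co1$traces))
    expect_identical(co1$traces[[id]]$values, co2$traces[[id]]$values)
  expect_error(paired_design(2, 1, focal_ids = c("a", "a"),
                             yoked_ids = c("b", "c")), "duplicate")
})

test_that("reference parameters produce a bimodal profile with ~2x nighttime long-bout sleep", {
  p <- test_params()
  n_flies <- 50
  day_lb <- night_lb <- numeric(n_flies)
  hourly <- matrix(0, n_flies, 24)
  for (i in seq_len(n_flies)) {
    tr <- generate_trace(p, n_days = 5, seed = 20000 + i)
    b <- detect_bouts(immobility_mask(tr))
    d_lb <- n_lb <- 0
    for (d in 1:5) {
      w <- day_window(d)
      mid <- w[1] + 4320L
      d_lb <- d_lb + sleep_time(b, 1500, c(w[1], mid))
      n_lb <- n_lb + sleep_time(b, 1500, c(mid, w[2]))
    }
    day_lb[i] <- d_lb / 5
    night_lb[i] <- n_lb / 5
    hourly[i, ] <- vapply(0:23, function(h) {
      mean(vapply(1:5, function(d) {
        w0 <- (d - 1L) * 8640L + h * 360L + 1L
        sleep_time(b, 300, c(w0, w0 + 360L))
      }, 0))
    }, 0)
  }
  ratio <- mean(night_lb) / mean(day_lb)
  expect_gte(ratio, 1.5)
  expect_lte(ratio, 2.5)
  # bimodality of the standard-sleep profile: a siesta peak (ZT4-9) above
  # the late-morning trough (ZT9-12), and a night peak above both
  prof <- colMeans(hourly)
  siesta <- max(prof[5:9])       # ZT4-8
  trough <- min(prof[9:12])      # ZT8-11
  night <- max(prof[13:24])      # ZT12-23
  expect_gt(siesta, trough)
  expect_gt(night, siesta)
})

test_that("24-h full deprivation is followed by a multi-day long-bout sleep surplus", {
  p <- test_params()
  cfg <- engine_config("inactivity_triggered", trigger_threshold_s = 220,
                       window_start_h = 24, window_h = 24)
  des <- paired_design(8, 0)
  run <- run_inactivity_triggered(des, p, n_days = 5, cfg = cfg, seed = 400)
  post <- c(day_window(3)[1], day_window(5)[2])
  surplus_std <- surplus_lb <- numeric(nrow(des$pairs))
  for (i in seq_len(nrow(des$pairs))) {
    id <- des$pairs$focal_id[i]
    twin <- somnoyoke:::simulate_fly(p, 5, somnoyoke:::substream_seed(400, id))
    bf <- detect_bouts(immobility_mask(run$cohort$traces[[id]]))
    bt <- detect_bouts(immobility_mask(fly_trace(twin$values, id)))
    surplus_std[i] <- sleep_time(bf, 300, post) - sleep_time(bt, 300, post)
    surplus_lb[i] <- sleep_time(bf, 1500, post) - sleep_time(bt, 1500, post)
  }
  # deprived flies sleep more over the following 3 days than their
  # unperturbed twins, and the surplus is concentrated in >= 25-min bouts
  expect_gt(mean(surplus_std), 0)
  expect_gt(mean(surplus_lb), 0)
  expect_gt(mean(surplus_lb), 0.5 * mean(surplus_std))
})

test_that("stimulation leaves a decaying locomotor elevation on the post-deprivation day", {
  p <- test_params()
  cfg <- engine_config("inactivity_triggered", trigger_threshold_s = 220,
                       window_start_h = 24, window_h = 24)
  des <- paired_design(8, 0)
  run <- run_inactivity_triggered(des, p, n_days = 3, cfg = cfg, seed = 812)
  elev <- matrix(0, nrow(des$pairs), 6)
  for (i in seq_len(nrow(des$pairs))) {
    id <- des$pairs$focal_id[i]
    twin <- somnoyoke:::simulate_fly(p, 3, somnoyoke:::substream_seed(812, id))
    w3 <- day_window(3)
    for (k in 1:6) {
      idx <- seq(w3[1] + (k - 1L) * 1440L, length.out = 1440L)
      elev[i, k] <- mean(run$cohort$traces[[id]]$values[idx]) -
        mean(twin$values[idx])
    }
  }
  blocks <- colMeans(elev)
  expect_gt(mean(blocks), 0)              # net post-day hyperactivity
  expect_gt(blocks[3] + blocks[4], 0)     # elevated around lights-off (ZT8-16)
})

test_that("DAM count emission is local, zero when immobile, and Poisson-mean calibrated", {
  quiet <- fly_trace(rep(0, 8640), "q")
  expect_true(all(to_dam_counts(quiet, 60) == 0))
  v <- rep(0, 8640); v[3000] <- 2  # one active epoch in an immobile day
  one <- fly_trace(v, "one")
  cts <- to_dam_counts(one, 60)
  expect_equal(sum(cts > 0), 1)
  expect_equal(which(cts > 0), (3000 - 1) %/% 6 + 1)
  # Poisson mean ~ lambda * speed over many bins
  v <- rep(3, 60 * 10000 / 10)
  tr <- fly_trace(rep(v, length.out = 8640 * 7)[1:(8640 * 7)], "m")
  cts <- to_dam_counts(tr, 60, lambda = 2, seed = 8)
  expect_equal(mean(cts), 2 * 3, tolerance = 0.02)
  expect_error(to_dam_counts(quiet, 25), "multiple")
})

test_that("velocity-path and DAM-path scoring agree on bin-aligned sleep", {
  # 15 consecutive zero 20-s bins form one 300-s bout under DAM scoring
  cts <- rep(5L, 180)
  cts[50:64] <- 0L
  b <- dam_sleep(cts, 20)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_s, 300)
  expect_equal(sleep_time(b, 300), 5)
  # a single nonzero bin splits the run
  cts2 <- cts; cts2[57] <- 1L
  expect_equal(nrow(dam_sleep(cts2, 20)), 2)
  expect_error(dam_sleep(c(1L, -1L), 20), "negative")
  # cross-modality: bin-aligned immobility converts losslessly
  v <- rep(2, 8640)
  v[1201:1800] <- 0   # 6000 s immobile, aligned to 60-s bins
  tr <- fly_trace(v, "x")
  cts3 <- to_dam_counts(tr, 60, seed = 2)
  expect_equal(sleep_time(dam_sleep(cts3, 60), 300),
               sleep_time(detect_bouts(immobility_mask(tr)), 300))
})
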