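test_that("BH adjustment matches the hand-computed step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- stats::p.adjust(p, method = "BH")  # the path test_peaks() uses
  expect_equal(q, rep(0.04, 4))
  expect_equal(q, oracle_bh(p))
  set.seed(3)
  for (i in 1:50) {
    pv <- runif(sample(3:40, 1))
    q <- stats::p.adjust(pv, "BH")
    expect_equal(q, oracle_bh(pv))
    expect_true(all(q >= pv))                    # q >= p
    expect_true(all(diff(q[order(pv)]) >= -1e-12))  # monotone in p
  }
})

test_that("all-constant intensities give p = 1 and all-NS calls", {
  m <- matrix(5, 20, 13)
  conds <- stats::setNames(rep(c("focal", "yoked", "unperturbed"),
                               c(6, 3, 4)), sprintf("s%02d", 1:13))
  tbl <- peak_table(m, conds)
  tests <- test_peaks(tbl, "yoked")
  expect_true(all(tests$p == 1))
  sc <- maldi_screen(tbl, "yoked")
  expect_equal(unname(sc$counts[["NS"]]), 20)
})

test_that("category logic implements the three search patterns with the omnibus gate", {
  expect_equal(classify_peak(c(FY = "higher", FU = "higher", YU = "higher"),
                             0.001), "sleep_pressure")
  expect_equal(classify_peak(c(FY = "ns", FU = "higher", YU = "higher"),
                             0.001), "mechanical")
  expect_equal(classify_peak(c(FY = "higher", FU = "higher", YU = "ns"),
                             0.001), "sleep_absence")
  expect_equal(classify_peak(c(FY = "lower", FU = "lower", YU = "ns"),
                             0.001), "other")
  # omnibus q >= alpha gates to NS regardless of pairwise pattern
  expect_equal(classify_peak(c(FY = "higher", FU = "higher", YU = "higher"),
                             0.2), "NS")
})

test_that("fixture generator plants ordered means, errors and warns as specified", {
  fix <- maldi_params(n_peaks = 20, n_sections = c(focal = 4, yoked = 4,
                                                   unperturbed = 4),
                      planted = c(NS = 5, mechanical = 5, sleep_pressure = 5,
                                  sleep_absence = 5, other = 0),
                      effect_size = 4, seed = 2)
  out <- generate_peak_table(fix)
  expect_true(all(out$table$intensities > 0))
  expect_equal(length(out$truth), 20)
  cond <- out$table$conditions
  for (mz in names(out$truth)[out$truth == "sleep_pressure"]) {
    x <- out$table$intensities[mz, ]
    gm <- tapply(log(x), cond, mean)
    expect_lt(gm[["unperturbed"]], gm[["yoked"]])
    expect_lt(gm[["yoked"]], gm[["focal"]])
  }
  expect_error(maldi_params(effect_size = -2), "positive")
  expect_warning(generate_peak_table(maldi_params(
    n_peaks = 10, n_sections = c(focal = 3, yoked = 3, unperturbed = 3),
    planted = c(NS = 5, mechanical = 5, sleep_pressure = 0,
                sleep_absence = 0, other = 0),
    effect_size = 1)), "NS")
})

test_that("screen recovers >= 90% of planted categories at effect 4x, n = 10/condition", {
  fix <- maldi_params(n_peaks = 100,
                      n_sections = c(focal = 10, yoked = 10,
                                     unperturbed = 10),
                      planted = c(NS = 40, mechanical = 25,
                                  sleep_pressure = 15, sleep_absence = 15,
                                  other = 5),
                      effect_size = 4, section_sdlog = 0.2, seed = 10)
  out <- generate_peak_table(fix)
  sc <- maldi_screen(out$table, "yoked")
  hit <- mean(sc$classification$category == unname(out$truth))
  expect_gte(hit, 0.9)
  # partition: category counts sum to the peak total
  expect_equal(sum(sc$counts), 100)
  # no-yoking mode collapses categories and partitions as well
  sc2 <- maldi_screen(out$table, "no_yoking")
  expect_equal(sum(sc2$counts), 100)
  expect_setequal(names(sc2$counts), c("positive_hit", "NS", "other_lower"))
  # planted "other" (focal lower) peaks land in other_lower
  low <- names(out$truth)[out$truth == "other"]
  expect_true(all(sc2$classification$category[
    sc2$classification$mz %in% low] == "other_lower"))
})

test_that("planted-category recovery is monotone in effect size and sample size", {
  recover <- function(effect, n_per) {
    fix <- maldi_params(n_peaks = 60,
                        n_sections = c(focal = n_per, yoked = n_per,
                                       unperturbed = n_per),
                        planted = c(NS = 20, mechanical = 15,
                                    sleep_pressure = 10, sleep_absence = 10,
                                    other = 5),
                        effect_size = effect, section_sdlog = 0.25,
                        seed = 77)
    out <- generate_peak_table(fix)
    mean(maldi_screen(out$table, "yoked")$classification$category ==
           unname(out$truth))
  }
  for (n_per in c(6, 10)) {
    r <- vapply(c(1.5, 2.5, 4), recover, 0, n_per = n_per)
    expect_true(all(diff(r) >= -0.02))  # non-decreasing (small MC slack)
  }
  expect_gte(recover(4, 10), recover(4, 6))
})

test_that("paper-scale section counts trigger the attainable-p QC flag yet the screen runs", {
  fix <- maldi_params(seed = 5)  # 6/3/4 sections, 188 peaks
  out <- generate_peak_table(fix)
  sc <- maldi_screen(out$table, "yoked")
  expect_equal(sum(sc$counts), 188)
  # exact rank-sum floors: focal(6) vs yoked(3) cannot beat Bonferroni 0.05
  fy <- sc$qc[sc$qc$comparison == "focal_vs_yoked", ]
  expect_equal(fy$p_floor, 2 / choose(9, 3))
  expect_false(fy$attainable)
})

test_that("null fixtures keep false-positive screens within the BH guarantee", {
  set.seed(31)
  n_draws <- 100
  any_fp <- logical(n_draws)
  for (i in seq_len(n_draws)) {
    fix <- maldi_params(n_peaks = 60,
                        n_sections = c(focal = 8, yoked = 8,
                                       unperturbed = 8),
                        planted = c(NS = 60, mechanical = 0,
                                    sleep_pressure = 0, sleep_absence = 0,
                                    other = 0),
                        effect_size = 4, seed = 1000 + i)
    out <- generate_peak_table(fix)
    sc <- maldi_screen(out$table, "yoked", alpha = 0.05)
    any_fp[i] <- any(sc$classification$category != "NS")
  }
  # under the global null, BH bounds P(any rejection) by alpha; allow the
  # binomial 95% half-width around 0.05 over 100 draws
  expect_lte(mean(any_fp), 0.05 + 1.96 * sqrt(0.05 * 0.95 / n_draws))
})

test_that("protonated-adduct arithmetic annotates serotonin at ~177 m/z", {
  expect_equal(serotonin_mz_check(176.2, "M+H"), 177.2, tolerance = 1e-4)
  expect_equal(serotonin_mz_check(0), 1.00728)
  expect_error(serotonin_mz_check(176.2, "M+Na"), "adduct")
  expect_true(match_adduct(177.1, 176.2))
  expect_false(match_adduct(177.5, 176.2))
})

test_that("peak tables round-trip through CSV + condition sidecar", {
  fix <- maldi_params(n_peaks = 12, n_sections = c(focal = 3, yoked = 3,
                                                   unperturbed = 3),
                      planted = c(NS = 6, mechanical = 3, sleep_pressure = 1,
                                  sleep_absence = 1, other = 1), seed = 4)
  out <- generate_peak_table(fix)
  path <- file.path(withr::local_tempdir(), "peaks.csv")
  write_peak_table(out$table, path)
  back <- read_peak_table(path)
  expect_equal(back$conditions, out$table$conditions)
  expect_equal(unname(back$intensities), unname(out$table$intensities),
               tolerance = 1e-8)
})
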