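# Homeostatic rebound quantification.
#
# Debt = baseline-day sleep minus sleep obtained inside the 24-h deprivation
# window. Post-deprivation gain on day d is normalized to unperturbed
# controls: (Focal_post_d - Focal_pre) - (mean Unperturbed_post_d -
# mean Unperturbed_pre); the unperturbed terms are day-matched cohort means,
# since the design pairs focal with yoked flies, not with unperturbed ones.
# Cumulative recovery fraction = cumulative normalized gain / debt, as a
# percentage (overshoot past 100% is meaningful and kept).

#' Sleep debt
#'
#' @param baseline_min total sleep (min) on the day before deprivation.
#' @param deprivation_min total sleep (min) during the deprivation window.
#' @return debt in minutes (`baseline - deprivation`).
#' @export
sleep_debt <- function(baseline_min, deprivation_min) {
  baseline_min - deprivation_min
}

#' Unperturbed-normalized sleep gain
#'
#' The printed normalization formula:
#' `(focal_post - focal_pre) - (unpert_post - unpert_pre)`, where the
#' unperturbed terms are day-matched cohort means.
#'
#' @param focal_pre,focal_post per-fly sleep (min) on the baseline day and a
#'   post-deprivation day.
#' @param unpert_pre,unpert_post unperturbed cohort-mean sleep (min) on the
#'   matching days.
#' @return normalized gain in minutes.
#' @export
normalized_gain <- function(focal_pre, focal_post, unpert_pre, unpert_post) {
  (focal_post - focal_pre) - (unpert_post - unpert_pre)
}

#' Cumulative recovery fraction
#'
#' @param cumulative_gain_min cumulative normalized sleep gain, minutes.
#' @param debt_min sleep debt, minutes. Non-positive debt makes the fraction
#'   undefined (`NA`), flagged with a warning.
#' @return recovery as a percentage of debt (values above 100 are kept:
#'   flies can overshoot their debt).
#' @export
recovery_fraction <- function(cumulative_gain_min, debt_min) {
  out <- 100 * cumulative_gain_min / debt_min
  bad <- !is.na(debt_min) & debt_min <= 0
  if (any(bad)) {
    warning(sum(bad), " value(s) with non-positive sleep debt: ",
            "recovery fraction undefined")
    out[bad] <- NA_real_
  }
  out
}

# internal: per-fly daily sleep (min) at one or more criteria.
# Returns a list with bouts per fly and a function day_sleep(id, day, k_s).
cohort_day_sleep <- function(cohort, threshold = 1.0) {
  bouts <- lapply(cohort$traces, function(tr)
    detect_bouts(immobility_mask(tr, threshold), tr$epoch_s))
  list(bouts = bouts,
       sleep = function(id, day, criterion_s)
         sleep_time(bouts[[id]], criterion_s, day_window(day)))
}

#' Per-fly rebound table
#'
#' Scores every fly of a deprivation run (or cohort) at one inactivity
#' criterion and tabulates, for each focal and yoked fly: baseline-day and
#' deprivation-window sleep, sleep debt, per-post-day raw and
#' unperturbed-normalized gains, cumulative gain, and cumulative recovery
#' fraction.
#'
#' @param x a `deprivation_run` (from [run_inactivity_triggered()]) or a
#'   `fly_cohort` whose design labels conditions.
#' @param criterion_s inactivity criterion, seconds.
#' @param baseline_day,deprivation_day day numbers (1-based) of the baseline
#'   and deprivation days.
#' @param n_post number of post-deprivation days to analyse.
#' @param threshold immobility threshold, mm/s.
#' @return data.frame of class `rebound_table`, one row per focal/yoked fly
#'   per post day, with columns `fly_id`, `condition`, `criterion_s`,
#'   `baseline_min`, `deprivation_min`, `debt_min`, `post_day`, `post_min`,
#'   `gain_raw_min`, `gain_min` (normalized), `cum_gain_min`,
#'   `cum_recovery_pct`.
#' @export
rebound_table <- function(x, criterion_s = 300, baseline_day = 1,
                          deprivation_day = 2, n_post = 3,
                          threshold = 1.0) {
  cohort <- if (inherits(x, "deprivation_run")) x$cohort else x
  stopifnot(inherits(cohort, "fly_cohort"))
  conds <- vapply(cohort$traces, `[[`, "", "condition")
  cds <- cohort_day_sleep(cohort, threshold)
  post_days <- deprivation_day + seq_len(n_post)
  u_ids <- names(conds)[conds == "unperturbed"]
  if (!length(u_ids))
    stop("rebound normalization requires unperturbed flies in the cohort")
  u_pre <- mean(vapply(u_ids, cds$sleep, 0, baseline_day, criterion_s))
  u_post <- vapply(post_days, function(d)
    mean(vapply(u_ids, cds$sleep, 0, d, criterion_s)), 0)

  rows <- list()
  for (id in names(conds)[conds %in% c("focal", "yoked")]) {
    base <- cds$sleep(id, baseline_day, criterion_s)
    dep <- cds$sleep(id, deprivation_day, criterion_s)
    debt <- sleep_debt(base, dep)
    post <- vapply(post_days, function(d) cds$sleep(id, d, criterion_s), 0)
    gain_raw <- post - base
    gain <- normalized_gain(base, post, u_pre, u_post)
    cum_gain <- cumsum(gain)
    rows[[id]] <- data.frame(
      fly_id = id, condition = conds[[id]], criterion_s = criterion_s,
      baseline_min = base, deprivation_min = dep, debt_min = debt,
      post_day = seq_len(n_post), post_min = post,
      gain_raw_min = gain_raw, gain_min = gain, cum_gain_min = cum_gain,
      cum_recovery_pct = if (debt > 0) 100 * cum_gain / debt
                         else rep(NA_real_, n_post),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  class(out) <- c("rebound_table", "data.frame")
  out
}

#' Criterion-sweep recovery surface
#'
#' Recomputes the cumulative unperturbed-normalized recovery fraction of
#' focal flies while sweeping the inactivity criterion (1-30 min by
#' default), producing the criterion x post-day surface whose structure
#' reveals which sleep state carries the homeostatic rebound. Cell (k, d) is
#' the mean over focal flies (with positive debt at criterion k) of
#' cumulative recovery through post day d, in percent.
#'
#' @param x a `deprivation_run` or `fly_cohort`.
#' @param criteria_min inactivity criteria to sweep, minutes.
#' @param n_post number of post-deprivation days.
#' @inheritParams rebound_table
#' @return matrix of class `sweep_surface` (criteria x post days) with a
#'   `qc_excluded` attribute counting flies excluded for non-positive debt
#'   at each criterion.
#' @export
criterion_sweep <- function(x, criteria_min = 1:30, n_post = 3,
                            baseline_day = 1, deprivation_day = 2,
                            threshold = 1.0) {
  if (!length(criteria_min)) stop("empty criterion list")
  cohort <- if (inherits(x, "deprivation_run")) x$cohort else x
  stopifnot(inherits(cohort, "fly_cohort"))
  conds <- vapply(cohort$traces, `[[`, "", "condition")
  f_ids <- names(conds)[conds == "focal"]
  u_ids <- names(conds)[conds == "unperturbed"]
  if (!length(f_ids)) stop("no focal flies in cohort")
  if (!length(u_ids)) stop("no unperturbed flies in cohort")
  cds <- cohort_day_sleep(cohort, threshold)
  post_days <- deprivation_day + seq_len(n_post)

  surface <- matrix(NA_real_, length(criteria_min), n_post,
                    dimnames = list(criterion_min = criteria_min,
                                    post_day = seq_len(n_post)))
  excluded <- integer(length(criteria_min))
  for (ki in seq_along(criteria_min)) {
    k_s <- criteria_min[ki] * 60
    u_pre <- mean(vapply(u_ids, cds$sleep, 0, baseline_day, k_s))
    u_post <- vapply(post_days, function(d)
      mean(vapply(u_ids, cds$sleep, 0, d, k_s)), 0)
    frac <- matrix(NA_real_, length(f_ids), n_post)
    ok <- logical(length(f_ids))
    for (fi in seq_along(f_ids)) {
      id <- f_ids[fi]
      base <- cds$sleep(id, baseline_day, k_s)
      debt <- base - cds$sleep(id, deprivation_day, k_s)
      if (debt <= 0) next
      ok[fi] <- TRUE
      post <- vapply(post_days, function(d) cds$sleep(id, d, k_s), 0)
      frac[fi, ] <- 100 * cumsum(normalized_gain(base, post, u_pre, u_post)) /
        debt
    }
    excluded[ki] <- sum(!ok)
    if (any(ok)) surface[ki, ] <- colMeans(frac[ok, , drop = FALSE])
  }
  attr(surface, "qc_excluded") <- stats::setNames(excluded,
                                                  paste0(criteria_min, "min"))
  class(surface) <- c("sweep_surface", class(surface))
  surface
}

#' @export
print.sweep_surface <- function(x, ...) {
  cat("<sweep_surface> mean cumulative recovery (%), criterion x post day\n")
  y <- x
  attr(y, "qc_excluded") <- NULL
  class(y) <- "matrix"
  print(round(unclass(y), 1))
  invisible(x)
}

#' Nonparametric group comparison
#'
#' Two groups: Wilcoxon rank-sum (Mann-Whitney U) test; the reported W is
#' the statistic of the first-named group, shown alongside group medians to
#' fix orientation. Three or more groups: Kruskal-Wallis omnibus test plus
#' Bonferroni-adjusted pairwise rank-sum tests.
#'
#' @param values numeric observations.
#' @param groups group labels, same length (first-appearance order defines
#'   the group order).
#' @return list of class `group_comparison`: `method`, `statistic`, `df`
#'   (Kruskal-Wallis only), `p_value`, `medians`, `n`, `pairwise`
#'   (data.frame, `NULL` for two groups... present with one row), and
#'   `small_groups` flagging groups with fewer than 2 observations.
#' @export
compare_groups <- function(values, groups) {
  groups <- factor(groups, levels = unique(as.character(groups)))
  stopifnot(length(values) == length(groups))
  n <- table(groups)
  if (length(n) < 2) stop("need at least 2 groups")
  small <- names(n)[n < 2]
  medians <- tapply(values, groups, stats::median)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   W = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    wt <- suppressWarnings(stats::wilcox.test(
      values[groups == pairs[1, i]], values[groups == pairs[2, i]]))
    pw$W[i] <- unname(wt$statistic)
    pw$p[i] <- wt$p.value
  }
  pw$p_adj <- stats::p.adjust(pw$p, method = "bonferroni")
  if (length(lv) == 2) {
    out <- list(method = "wilcoxon_rank_sum", statistic = pw$W[1],
                df = NA_integer_, p_value = pw$p[1])
  } else {
    kw <- stats::kruskal.test(values, groups)
    out <- list(method = "kruskal_wallis", statistic = unname(kw$statistic),
                df = unname(kw$parameter), p_value = kw$p.value)
  }
  out$medians <- medians
  out$n <- n
  out$pairwise <- pw
  out$small_groups <- small
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$method == "wilcoxon_rank_sum")
    cat(sprintf("<group_comparison> Wilcoxon rank sum: W = %g, p = %.4g\n",
                x$statistic, x$p_value))
  else
    cat(sprintf("<group_comparison> Kruskal-Wallis: H = %.3f, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  cat("  medians:", paste(sprintf("%s = %.3g", names(x$medians), x$medians),
                          collapse = ", "), "\n")
  if (x$method != "wilcoxon_rank_sum") {
    cat("  Bonferroni-adjusted pairwise rank-sum tests:\n")
    print(x$pairwise, row.names = FALSE)
  }
  if (length(x$small_groups))
    cat("  flagged (n < 2):", paste(x$small_groups, collapse = ", "), "\n")
  invisible(x)
}

#' Two-way fixed-factor ANOVA with interaction
#'
#' Tests whether the post-deprivation sleep gain of disturbed vs unperturbed
#' flies depends on the stimulation frequency: a treatment x frequency ANOVA
#' whose interaction term carries the inference.
#'
#' @param data data.frame with the response and the two factors.
#' @param response name of the response column (sleep gain, min).
#' @param treatment name of the two-level treatment factor.
#' @param frequency name of the trigger-frequency factor.
#' @return data.frame of class `anova_report` with one row per term
#'   (`treatment`, `frequency`, `interaction`, `residuals`): `df`, `sum_sq`,
#'   `F`, `p`.
#' @export
interaction_anova <- function(data, response = "gain",
                              treatment = "treatment",
                              frequency = "frequency") {
  stopifnot(all(c(response, treatment, frequency) %in% names(data)))
  a <- factor(data[[treatment]])
  b <- factor(data[[frequency]])
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("both factors need at least 2 levels")
  if (any(table(a, b) == 0)) stop("empty treatment x frequency cell")
  y <- data[[response]]
  if (stats::var(y) == 0 && length(unique(paste(a, b))) == 1)
    stop("single-cell constant data")
  fit <- stats::aov(y ~ a * b)
  s <- summary(fit)[[1]]
  out <- data.frame(term = c("treatment", "frequency", "interaction",
                             "residuals"),
                    df = s$Df, sum_sq = s$`Sum Sq`,
                    F = s$`F value`, p = s$`Pr(>F)`)
  class(out) <- c("anova_report", "data.frame")
  out
}
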