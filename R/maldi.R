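# Three-condition MALDI-TOF peak-pattern screen.
#
# Input: an m/z-peak x brain-ROI-section intensity table with sections
# labelled focal / yoked / unperturbed. Per peak, an omnibus test gated at a
# Benjamini-Hochberg q < alpha across the peak family, then
# Bonferroni-adjusted pairwise rank-sum tests within the peak decide the
# category:
#   mechanical     focal > unpert and yoked > unpert significant, focal-yoked
#                  indistinguishable (a stimulus artifact);
#   sleep_pressure unpert < yoked < focal, all pairs distinguishable;
#   sleep_absence  focal above both, yoked ~ unpert (tracks the complete
#                  absence of sleep, not graded pressure);
#   NS             omnibus q >= alpha;
#   other          any remaining pattern (including focal lower).
# "Similar/indistinguishable" is operationalized as pairwise
# non-significance after correction - an accept-the-null convention,
# documented as a limitation.

MALDI_CATEGORIES <- c("NS", "mechanical", "sleep_pressure", "sleep_absence",
                      "other")
PROTON_MASS <- 1.00728

#' Construct a peak-intensity table
#'
#' @param intensities numeric matrix, peaks x sections, strictly positive;
#'   rownames are m/z labels (one decimal), colnames section ids.
#' @param conditions named character vector mapping each section id to
#'   `"focal"`, `"yoked"` or `"unperturbed"`.
#' @return object of class `peak_table`.
#' @export
peak_table <- function(intensities, conditions) {
  intensities <- as.matrix(intensities)
  if (anyNA(intensities)) stop("peak table must have no missing cells")
  if (any(intensities <= 0)) stop("intensities must be strictly positive")
  if (is.null(colnames(intensities))) {
    colnames(intensities) <-
      if (!is.null(names(conditions)) &&
          length(conditions) == ncol(intensities)) names(conditions)
      else sprintf("sec_%02d", seq_len(ncol(intensities)))
  }
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("%.1f", seq_len(nrow(intensities)))
  conditions <- conditions[colnames(intensities)]
  if (anyNA(conditions))
    stop("every section needs a condition label")
  if (!all(conditions %in% c("focal", "yoked", "unperturbed")))
    stop("conditions must be focal / yoked / unperturbed")
  tab <- table(factor(conditions,
                      levels = c("focal", "yoked", "unperturbed")))
  if (any(tab[tab > 0] < 2))
    stop("need at least 2 sections per included condition")
  structure(list(intensities = intensities,
                 conditions = as.character(conditions),
                 section_ids = colnames(intensities),
                 mz = rownames(intensities)),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  tab <- table(x$conditions)
  cat(sprintf("<peak_table> %d peaks x %d sections (%s)\n",
              nrow(x$intensities), length(x$conditions),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' MALDI fixture parameters
#'
#' Parameters of the synthetic peak-table generator. Defaults mirror the
#' reference screen: 188 peaks; sections per condition 6 focal / 3 yoked /
#' 4 unperturbed; planted category counts 85 NS, 73 mechanical, 8
#' sleep-pressure, 9 sleep-absence, 13 other. Planted effects are
#' multiplicative on a lognormal baseline: mechanical peaks are elevated
#' equally in focal and yoked sections, sleep-pressure peaks are ordered
#' unperturbed < yoked (sqrt of the effect) < focal, sleep-absence peaks are
#' elevated in focal only, and "other" peaks are lowered in focal.
#'
#' @param n_peaks total peak count.
#' @param n_sections named counts of sections per condition.
#' @param planted named counts per category (must sum to `n_peaks`).
#' @param effect_size multiplicative condition effect (> 0; 1 = null).
#' @param baseline_meanlog,baseline_sdlog lognormal location/spread of
#'   per-peak baseline intensity.
#' @param section_sdlog within-peak section-to-section spread (log units).
#' @param seed RNG seed.
#' @return object of class `maldi_params`.
#' @export
maldi_params <- function(n_peaks = 188,
                         n_sections = c(focal = 6, yoked = 3,
                                        unperturbed = 4),
                         planted = c(NS = 85, mechanical = 73,
                                     sleep_pressure = 8, sleep_absence = 9,
                                     other = 13),
                         effect_size = 4,
                         baseline_meanlog = log(1000),
                         baseline_sdlog = 1,
                         section_sdlog = 0.2,
                         seed = 1L) {
  if (effect_size <= 0) stop("effect_size must be positive")
  if (any(n_sections < 2)) stop("need at least 2 sections per condition")
  if (!setequal(names(planted), MALDI_CATEGORIES) ||
      sum(planted) != n_peaks)
    stop("planted category counts must cover ",
         paste(MALDI_CATEGORIES, collapse = "/"),
         " and sum to n_peaks")
  structure(list(n_peaks = as.integer(n_peaks),
                 n_sections = n_sections, planted = planted,
                 effect_size = effect_size,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 section_sdlog = section_sdlog, seed = as.integer(seed)),
            class = "maldi_params")
}

# internal: per-category multiplicative condition effects
category_multipliers <- function(category, effect) {
  switch(category,
         NS             = c(focal = 1, yoked = 1, unperturbed = 1),
         mechanical     = c(focal = effect, yoked = effect, unperturbed = 1),
         sleep_pressure = c(focal = effect, yoked = sqrt(effect),
                            unperturbed = 1),
         sleep_absence  = c(focal = effect, yoked = 1, unperturbed = 1),
         other          = c(focal = 1 / effect, yoked = 1, unperturbed = 1))
}

#' Generate a synthetic peak table with planted categories
#'
#' @param fix a [maldi_params()] object.
#' @param seed RNG seed override (defaults to `fix$seed`).
#' @return list with `table` (a [peak_table()]) and `truth` (character
#'   vector of planted categories, named by m/z label). With
#'   `effect_size = 1` every peak is generated as NS regardless of the
#'   requested labels and a consistency warning is raised.
#' @export
generate_peak_table <- function(fix = maldi_params(), seed = fix$seed) {
  set.seed(as.integer(seed))
  truth <- rep(names(fix$planted), fix$planted)
  truth <- sample(truth)  # shuffle category positions across m/z
  if (fix$effect_size == 1 && any(truth != "NS")) {
    warning("effect_size = 1: all peaks are generated as NS regardless of ",
            "the planted labels")
    truth[] <- "NS"
  }
  mz <- sprintf("%.1f", sort(stats::runif(fix$n_peaks, 50, 1300)))
  while (anyDuplicated(mz))
    mz[duplicated(mz)] <- sprintf("%.1f",
                                  as.numeric(mz[duplicated(mz)]) + 0.1)
  conditions <- rep(names(fix$n_sections), fix$n_sections)
  sections <- sprintf("%s_s%02d", conditions,
                      unlist(lapply(fix$n_sections, seq_len)))
  base <- exp(stats::rnorm(fix$n_peaks, fix$baseline_meanlog,
                           fix$baseline_sdlog))
  m <- matrix(0, fix$n_peaks, length(sections),
              dimnames = list(mz, sections))
  for (i in seq_len(fix$n_peaks)) {
    mult <- category_multipliers(truth[i], fix$effect_size)
    m[i, ] <- base[i] * mult[conditions] *
      exp(stats::rnorm(length(sections), 0, fix$section_sdlog))
  }
  list(table = peak_table(m, stats::setNames(conditions, sections)),
       truth = stats::setNames(truth, mz))
}

#' Per-peak omnibus tests with Benjamini-Hochberg correction
#'
#' Mode `"yoked"` runs a Kruskal-Wallis test across the three conditions per
#' peak; mode `"no_yoking"` discards the yoked sections and runs a two-group
#' rank-sum test of focal vs unperturbed. Raw p-values are BH-adjusted
#' across the whole peak family.
#'
#' @param table a [peak_table()].
#' @param mode `"yoked"` or `"no_yoking"`.
#' @return data.frame with `mz`, `p`, `q`.
#' @export
test_peaks <- function(table, mode = c("yoked", "no_yoking")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "peak_table"))
  cond <- table$conditions
  need <- if (mode == "yoked") c("focal", "yoked", "unperturbed")
          else c("focal", "unperturbed")
  if (!all(need %in% cond))
    stop("mode '", mode, "' requires sections for: ",
         paste(need, collapse = ", "))
  p <- apply(table$intensities, 1, function(x) {
    if (stats::var(x) == 0) return(1)
    if (mode == "yoked")
      stats::kruskal.test(x, factor(cond))$p.value
    else
      suppressWarnings(stats::wilcox.test(x[cond == "focal"],
                                          x[cond == "unperturbed"]))$p.value
  })
  data.frame(mz = table$mz, p = unname(p),
             q = stats::p.adjust(unname(p), method = "BH"),
             stringsAsFactors = FALSE)
}

#' Classify one peak from its pairwise decisions
#'
#' @param decisions named character vector with elements `FY`, `FU`, `YU`,
#'   each `"higher"`, `"lower"` or `"ns"` - the Bonferroni-adjusted pairwise
#'   rank-sum outcome for focal-vs-yoked, focal-vs-unperturbed and
#'   yoked-vs-unperturbed (direction = sign of the first-named group's
#'   median difference).
#' @param omnibus_q BH-adjusted omnibus q-value of the peak.
#' @param alpha significance level.
#' @return one of `"NS"`, `"mechanical"`, `"sleep_pressure"`,
#'   `"sleep_absence"`, `"other"`.
#' @export
classify_peak <- function(decisions, omnibus_q, alpha = 0.05) {
  if (omnibus_q >= alpha) return("NS")
  fy <- decisions[["FY"]]; fu <- decisions[["FU"]]; yu <- decisions[["YU"]]
  if (fu == "higher" && yu == "higher" && fy == "ns") return("mechanical")
  if (fy == "higher" && yu == "higher" && fu == "higher")
    return("sleep_pressure")
  if (fy == "higher" && fu == "higher" && yu == "ns") return("sleep_absence")
  "other"
}

# internal: pairwise decision for two section groups
pairwise_decision <- function(x1, x2, alpha) {
  p <- suppressWarnings(stats::wilcox.test(x1, x2))$p.value
  p_adj <- min(1, p * 3)  # Bonferroni over the 3 within-peak comparisons
  if (is.na(p_adj) || p_adj >= alpha) return("ns")
  d <- stats::median(x1) - stats::median(x2)
  if (d > 0) "higher" else if (d < 0) "lower" else "ns"
}

# internal: smallest attainable two-sided exact rank-sum p for group sizes
rank_sum_p_floor <- function(n1, n2) {
  min(1, 2 / choose(n1 + n2, n1))
}

#' Run the full peak-pattern screen
#'
#' Omnibus tests ([test_peaks()]) gated at BH q < `alpha`, then
#' Bonferroni-adjusted pairwise rank-sum tests within each significant peak,
#' and category calls per [classify_peak()]. In `"no_yoking"` mode the
#' categories collapse to `positive_hit` (focal significantly higher than
#' unperturbed), `other_lower` (significantly lower) and `NS`.
#'
#' @param table a [peak_table()].
#' @param mode `"yoked"` or `"no_yoking"`.
#' @param alpha omnibus (BH) significance level.
#' @param posthoc_alpha pairwise significance level (defaults to `alpha`).
#' @return object of class `maldi_screen`: list with `classification`
#'   (per-peak data.frame), `counts`, `percentages`, `mode`, `alpha`, and
#'   `qc` (attainable-p floors per pairwise comparison given the section
#'   counts, with a note when a floor exceeds the post-hoc alpha).
#' @export
maldi_screen <- function(table, mode = c("yoked", "no_yoking"),
                         alpha = 0.05, posthoc_alpha = alpha) {
  mode <- match.arg(mode)
  tests <- test_peaks(table, mode)
  cond <- table$conditions
  n <- table(factor(cond, levels = c("focal", "yoked", "unperturbed")))
  if (mode == "yoked") {
    cats <- character(nrow(tests))
    dec <- matrix("ns", nrow(tests), 3,
                  dimnames = list(NULL, c("FY", "FU", "YU")))
    for (i in seq_len(nrow(tests))) {
      if (tests$q[i] >= alpha) { cats[i] <- "NS"; next }
      x <- table$intensities[i, ]
      dec[i, "FY"] <- pairwise_decision(x[cond == "focal"],
                                        x[cond == "yoked"], posthoc_alpha)
      dec[i, "FU"] <- pairwise_decision(x[cond == "focal"],
                                        x[cond == "unperturbed"],
                                        posthoc_alpha)
      dec[i, "YU"] <- pairwise_decision(x[cond == "yoked"],
                                        x[cond == "unperturbed"],
                                        posthoc_alpha)
      cats[i] <- classify_peak(dec[i, ], tests$q[i], alpha)
    }
    classification <- cbind(tests, as.data.frame(dec),
                            category = cats, stringsAsFactors = FALSE)
    levels_out <- MALDI_CATEGORIES
    qc <- data.frame(
      comparison = c("focal_vs_yoked", "focal_vs_unperturbed",
                     "yoked_vs_unperturbed"),
      p_floor = c(rank_sum_p_floor(n[["focal"]], n[["yoked"]]),
                  rank_sum_p_floor(n[["focal"]], n[["unperturbed"]]),
                  rank_sum_p_floor(n[["yoked"]], n[["unperturbed"]])))
    qc$bonferroni_floor <- pmin(1, qc$p_floor * 3)
    qc$attainable <- qc$bonferroni_floor < posthoc_alpha
  } else {
    med_f <- apply(table$intensities[, cond == "focal", drop = FALSE], 1,
                   stats::median)
    med_u <- apply(table$intensities[, cond == "unperturbed", drop = FALSE],
                   1, stats::median)
    cats <- ifelse(tests$q >= alpha, "NS",
                   ifelse(med_f > med_u, "positive_hit", "other_lower"))
    classification <- cbind(tests, category = cats, stringsAsFactors = FALSE)
    levels_out <- c("positive_hit", "NS", "other_lower")
    qc <- data.frame(comparison = "focal_vs_unperturbed",
                     p_floor = rank_sum_p_floor(n[["focal"]],
                                                n[["unperturbed"]]))
    qc$bonferroni_floor <- qc$p_floor
    qc$attainable <- qc$p_floor < alpha
  }
  counts <- table(factor(classification$category, levels = levels_out))
  structure(list(classification = classification,
                 counts = counts,
                 percentages = category_percentages(counts),
                 mode = mode, alpha = alpha, posthoc_alpha = posthoc_alpha,
                 qc = qc),
            class = "maldi_screen")
}

#' Category percentages from category counts
#'
#' The tabulation/percentage path used to report screen outcomes: shares of
#' the total peak count, in percent.
#'
#' @param counts named numeric vector (or table) of per-category peak
#'   counts.
#' @return named numeric vector of percentages summing to 100; attribute
#'   `total` carries the total peak count.
#' @export
category_percentages <- function(counts) {
  counts <- c(counts)
  total <- sum(counts)
  if (total <= 0) stop("no peaks counted")
  structure(100 * counts / total, total = total)
}

#' @export
print.maldi_screen <- function(x, ...) {
  cat(sprintf("<maldi_screen> mode %s, alpha %.3g: %d peaks\n", x$mode,
              x$alpha, sum(x$counts)))
  for (nm in names(x$counts))
    cat(sprintf("  %-14s %4d (%.1f%%)\n", nm, x$counts[[nm]],
                x$percentages[[nm]]))
  if (any(!x$qc$attainable))
    cat("  QC: some pairwise tests cannot reach significance at these\n",
        "     section counts (exact rank-sum p floors above alpha)\n")
  invisible(x)
}

#' m/z of a protonated adduct
#'
#' Positive-ion matrices such as DHB add a single proton; a neutral mass m
#' appears at m/z = m + 1.007. Serotonin (average mass 176.2) is expected at
#' ~177.2.
#'
#' @param mass neutral (monoisotopic or average) mass in Da.
#' @param adduct adduct type; only `"M+H"` is supported.
#' @return expected m/z.
#' @export
serotonin_mz_check <- function(mass = 176.2, adduct = "M+H") {
  if (!identical(adduct, "M+H")) stop("unknown adduct: ", adduct)
  stopifnot(is.numeric(mass), mass >= 0)
  mass + PROTON_MASS
}

#' Annotate peaks matching an adduct m/z
#'
#' @param mz numeric vector of observed peak m/z values.
#' @param mass neutral mass to match.
#' @param adduct adduct type (see [serotonin_mz_check()]).
#' @param tol match tolerance in Da (default +/- 0.2).
#' @return logical vector: which peaks fall within `tol` of the adduct m/z.
#' @export
match_adduct <- function(mz, mass = 176.2, adduct = "M+H", tol = 0.2) {
  abs(as.numeric(mz) - serotonin_mz_check(mass, adduct)) <= tol
}

#' Write / read a peak table as CSV plus a condition sidecar
#'
#' The main CSV has the m/z label in the first column and one column per
#' section; the sidecar CSV maps section id to condition.
#'
#' @param table a [peak_table()].
#' @param path main CSV path; the sidecar is written next to it as
#'   `<path>_conditions.csv`.
#' @return `path`, invisibly (writer); a [peak_table()] (reader).
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  df <- data.frame(mz = table$mz, table$intensities, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- data.frame(section_id = table$section_ids,
                     condition = table$conditions)
  utils::write.csv(side, sidecar_path(path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- utils::read.csv(sidecar_path(path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  peak_table(m, stats::setNames(as.character(side$condition),
                                side$section_id))
}

sidecar_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_conditions.csv")
}
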