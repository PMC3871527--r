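#' ROI summary of one paired test/retest study
#'
#' Reduces the parameter maps of one animal to per-session summaries over
#' the model-3 region (the only region where vp, Ktrans and ve are all
#' defined) and emits the test-retest difference in both absolute
#' (retest - test) and percent (100 (retest - test)/test) modes.
#'
#' @param pair A `study_pair`: list with `animal_id`, `group_h`, and `test`
#'   / `retest` elements each holding maps from [make_masked_maps()].
#' @param statistic `"mean"` or `"median"` across ROI voxels.
#' @param mask_rule Which model-3 mask defines the ROI: `"test"`,
#'   `"retest"` or their `"intersection"` (default).
#' @return One-row data.frame: identifiers, per-session summaries of vp,
#'   Ktrans, ve, absolute and percent differences, ROI voxel count, and an
#'   `excluded` flag with `reason` when the mask is empty.
#' @export
summarize_roi <- function(pair, statistic = c("mean", "median"),
                          mask_rule = c("intersection", "test", "retest")) {
  statistic <- match.arg(statistic)
  mask_rule <- match.arg(mask_rule)
  stat_fun <- if (statistic == "mean") mean else median
  m <- switch(mask_rule,
              test = pair$test$mask3,
              retest = pair$retest$mask3,
              intersection = pair$test$mask3 & pair$retest$mask3)
  row <- data.frame(animal_id = pair$animal_id, group_h = pair$group_h,
                    n_roi = sum(m), excluded = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  params <- c("vp", "ktrans", "ve")
  for (p in params) {
    for (s in c("test", "retest"))
      row[[paste0(p, "_", s)]] <- NA_real_
    row[[paste0("d_abs_", p)]] <- NA_real_
    row[[paste0("d_pct_", p)]] <- NA_real_
  }
  if (sum(m) == 0) {
    row$excluded <- TRUE
    row$reason <- "no Model-3 voxels under mask rule"
    return(row)
  }
  for (p in params) {
    a <- stat_fun(pair$test[[p]][m], na.rm = TRUE)
    b <- stat_fun(pair$retest[[p]][m], na.rm = TRUE)
    row[[paste0(p, "_test")]] <- a
    row[[paste0(p, "_retest")]] <- b
    row[[paste0("d_abs_", p)]] <- b - a
    row[[paste0("d_pct_", p)]] <- if (is.finite(a) && a != 0)
      100 * (b - a) / a else NA_real_
  }
  row
}

#' Build the cohort table from per-animal summaries
#'
#' @param rows List of one-row data.frames from [summarize_roi()].
#' @return data.frame with one row per animal (excluded rows retained and
#'   flagged).
#' @export
cohort_table <- function(rows) {
  do.call(rbind, rows)
}

diff_column <- function(parameter = c("ktrans", "ve", "vp"),
                        mode = c("absolute", "percent")) {
  parameter <- match.arg(parameter)
  mode <- match.arg(mode)
  paste0(if (mode == "absolute") "d_abs_" else "d_pct_", parameter)
}

#' Paired t-test of the treatment effect at each time point
#'
#' Within each treatment-time group, tests whether the retest summaries
#' differ from the test summaries (paired, two-sided). Zero-variance
#' difference sets are flagged rather than producing an undefined t.
#'
#' @param table Cohort table from [cohort_table()].
#' @param parameter `"ktrans"`, `"ve"` or `"vp"`.
#' @param mode `"absolute"` or `"percent"` difference scale.
#' @return data.frame per group: `group_h`, `n`, mean difference, `t`,
#'   `df`, `p`, and `zero_variance` flag.
#' @export
paired_t_per_group <- function(table, parameter = "ktrans",
                               mode = "absolute") {
  col <- diff_column(parameter, mode)
  tab <- table[!table$excluded, ]
  groups <- sort(unique(tab$group_h))
  rows <- lapply(groups, function(h) {
    d <- tab[tab$group_h == h, col]
    d <- d[!is.na(d)]
    n <- length(d)
    if (n < 2) stop("paired t-test needs n >= 2 per group")
    if (sd(d) == 0) {
      return(data.frame(group_h = h, n = n, mean_diff = mean(d),
                        t = NA_real_, df = n - 1, p = NA_real_,
                        zero_variance = TRUE))
    }
    tt <- t.test(d)  # one-sample t on differences == paired t
    data.frame(group_h = h, n = n, mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, zero_variance = FALSE)
  })
  do.call(rbind, rows)
}

#' One-way ANOVA across treatment times with a planned contrast
#'
#' Fits a one-way ANOVA of the test-retest differences on treatment-time
#' group and tests the planned contrast comparing the pooled early groups
#' with the pooled late groups using the ANOVA pooled error (MSE on
#' N - k df). The contrast estimate is
#' `mean(pooled early animals) - mean(pooled late animals)`, i.e. group
#' means weighted by group size.
#'
#' @param table Cohort table from [cohort_table()].
#' @param parameter,mode As in [paired_t_per_group()].
#' @param contrast List with numeric vectors `plus` and `minus` naming the
#'   groups (h) pooled on each side.
#' @return List with the overall ANOVA (`f`, `df1`, `df2`, `p_overall`,
#'   sums of squares) and the contrast (`estimate`, `se`, `t`, `df`, `p`).
#' @export
anova_with_contrast <- function(table, parameter = "ktrans",
                                mode = "absolute",
                                contrast = list(plus = c(2, 4),
                                                minus = c(12, 24))) {
  col <- diff_column(parameter, mode)
  tab <- table[!table$excluded & !is.na(table[[col]]), ]
  d <- tab[[col]]
  g <- factor(tab$group_h)
  k <- nlevels(g)
  if (k < 2) stop("ANOVA needs at least two groups")
  if (any(tabulate(g) < 2)) stop("ANOVA needs n >= 2 per group")
  if (!all(c(contrast$plus, contrast$minus) %in% tab$group_h))
    stop("contrast names a group missing from the table")
  N <- length(d)
  fit <- aov(d ~ g)
  an <- anova(fit)
  ss_between <- an[["Sum Sq"]][1]
  ss_within <- an[["Sum Sq"]][2]
  mse <- an[["Mean Sq"]][2]
  f_overall <- an[["F value"]][1]
  p_overall <- an[["Pr(>F)"]][1]

  gh <- as.numeric(levels(g))
  n_g <- tabulate(g)
  means <- tapply(d, g, mean)
  n_plus <- sum(n_g[gh %in% contrast$plus])
  n_minus <- sum(n_g[gh %in% contrast$minus])
  # pooled-animal means: coefficients n_g/n_plus on the early side etc.
  w <- ifelse(gh %in% contrast$plus, n_g / n_plus,
              ifelse(gh %in% contrast$minus, -n_g / n_minus, 0))
  stopifnot(abs(sum(w)) < 1e-12)
  est <- sum(w * means)
  se <- sqrt(mse * sum(w^2 / n_g))
  tstat <- est / se
  df <- N - k
  p <- 2 * pt(-abs(tstat), df)
  list(parameter = parameter, mode = mode,
       anova = list(f = f_overall, df1 = k - 1, df2 = df,
                    p_overall = p_overall, ss_between = ss_between,
                    ss_within = ss_within, ss_total = ss_between + ss_within,
                    mse = mse),
       contrast = list(plus = contrast$plus, minus = contrast$minus,
                       n_plus = n_plus, n_minus = n_minus,
                       estimate = est, se = se, t = tstat, df = df, p = p))
}

#' Pooled-group summary of test-retest differences
#'
#' Mean and SD of the per-animal differences pooled over groups, the
#' summary layout used for reporting early (2 and 4 h) versus late
#' (12 and 24 h) treatment effects.
#'
#' @param table Cohort table.
#' @param pools Named list of group vectors to pool.
#' @param mode Difference mode.
#' @return data.frame: pool name, parameter, `n`, `mean`, `sd`.
#' @export
pooled_differences <- function(table,
                               pools = list("2 and 4 hour" = c(2, 4),
                                            "12 and 24 hour" = c(12, 24)),
                               mode = "absolute") {
  tab <- table[!table$excluded, ]
  rows <- list()
  for (pn in names(pools)) {
    sel <- tab$group_h %in% pools[[pn]]
    for (p in c("ktrans", "ve", "vp")) {
      d <- tab[sel, diff_column(p, mode)]
      d <- d[!is.na(d)]
      rows[[length(rows) + 1]] <-
        data.frame(pool = pn, parameter = p, n = length(d),
                   mean = mean(d), sd = sd(d))
    }
  }
  do.call(rbind, rows)
}

#' Boxplot-ready distribution summaries of differences by group
#'
#' Quartiles with Tukey whiskers (most extreme points within 1.5 IQR of
#' the quartiles) and outliers, machine-readable for plotting.
#'
#' @param table Cohort table.
#' @param parameter,mode As in [paired_t_per_group()].
#' @return List of data.frames: `stats` (per group: n, median, q1, q3,
#'   whisker_lo, whisker_hi) and `outliers` (group, value).
#' @export
export_boxplot_data <- function(table, parameter = "ktrans",
                                mode = "percent") {
  col <- diff_column(parameter, mode)
  tab <- table[!table$excluded & !is.na(table[[col]]), ]
  if (!nrow(tab)) stop("no data to summarise")
  groups <- sort(unique(tab$group_h))
  stats <- list(); outs <- list()
  for (h in groups) {
    d <- sort(tab[tab$group_h == h, col])
    q1 <- unname(quantile(d, 0.25)); q3 <- unname(quantile(d, 0.75))
    iqr <- q3 - q1
    in_lo <- d[d >= q1 - 1.5 * iqr]
    in_hi <- d[d <= q3 + 1.5 * iqr]
    stats[[length(stats) + 1]] <-
      data.frame(group_h = h, n = length(d), median = median(d),
                 q1 = q1, q3 = q3,
                 whisker_lo = min(in_lo), whisker_hi = max(in_hi))
    out <- d[d < q1 - 1.5 * iqr | d > q3 + 1.5 * iqr]
    if (length(out))
      outs[[length(outs) + 1]] <- data.frame(group_h = h, value = out)
  }
  list(stats = do.call(rbind, stats),
       outliers = if (length(outs)) do.call(rbind, outs)
                  else data.frame(group_h = numeric(), value = numeric()))
}
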