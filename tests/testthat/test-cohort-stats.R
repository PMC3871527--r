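maps_const <- function(vp, kt, ve, dims = c(2, 2, 1)) {
  list(vp = array(vp, dims), ktrans = array(kt, dims), ve = array(ve, dims),
       kep = array(kt / ve, dims), order = array(3L, dims),
       mask3 = array(TRUE, dims))
}

toy_table <- function() {
  # five groups, three animals each, differences laid out by hand
  set.seed(123)
  rows <- list()
  for (h in c(2, 4, 8, 12, 24)) {
    for (i in 1:3) {
      d <- rnorm(1, ifelse(h < 8, 0.005, ifelse(h > 8, -0.004, 0)), 0.002)
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = sprintf("%d_%d", h, i), group_h = h, n_roi = 10,
        excluded = FALSE, reason = "",
        ktrans_test = 0.02, ktrans_retest = 0.02 + d,
        d_abs_ktrans = d, d_pct_ktrans = 100 * d / 0.02,
        ve_test = 0.1, ve_retest = 0.1 + d, d_abs_ve = d,
        d_pct_ve = 100 * d / 0.1,
        vp_test = 0.02, vp_retest = 0.02 + d / 5, d_abs_vp = d / 5,
        d_pct_vp = 100 * (d / 5) / 0.02)
    }
  }
  cohort_table(rows)
}

test_that("identical test and retest maps give zero differences in both modes", {
  m <- maps_const(0.02, 0.02, 0.1)
  pair <- list(animal_id = "A", group_h = 8, test = m, retest = m)
  row <- summarize_roi(pair)
  expect_equal(row$d_abs_ktrans, 0)
  expect_equal(row$d_pct_ktrans, 0)
  expect_equal(row$d_abs_ve, 0)
})

test_that("difference arithmetic: 0.010 to 0.015 is +0.005 absolute, +50%", {
  pair <- list(animal_id = "A", group_h = 2,
               test = maps_const(0.02, 0.010, 0.1),
               retest = maps_const(0.02, 0.015, 0.1))
  row <- summarize_roi(pair)
  expect_equal(row$d_abs_ktrans, 0.005, tolerance = 1e-12)
  expect_equal(row$d_pct_ktrans, 50, tolerance = 1e-9)
})

test_that("mask rules pick the requested session masks", {
  m_t <- maps_const(0.02, 0.01, 0.1)
  m_r <- maps_const(0.02, 0.02, 0.1)
  m_r$mask3[1, 1, 1] <- FALSE
  pair <- list(animal_id = "A", group_h = 2, test = m_t, retest = m_r)
  expect_equal(summarize_roi(pair, mask_rule = "test")$n_roi, 4)
  expect_equal(summarize_roi(pair, mask_rule = "retest")$n_roi, 3)
  expect_equal(summarize_roi(pair, mask_rule = "intersection")$n_roi, 3)
})

test_that("paired t on differences 1, 2, 3 gives t = 3.4641 with df 2", {
  rows <- lapply(1:3, function(i)
    data.frame(animal_id = i, group_h = 8, n_roi = 1, excluded = FALSE,
               reason = "", d_abs_ktrans = i, d_pct_ktrans = NA))
  tab <- cohort_table(rows)
  res <- paired_t_per_group(tab, "ktrans", "absolute")
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-4)
  expect_equal(res$df, 2)
  # closed form: t = mean/ (sd/sqrt(n)) = 2 / (1/sqrt(3))
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
})

test_that("paired t is invariant to animal order and flags zero variance", {
  tab <- toy_table()
  res1 <- paired_t_per_group(tab, "ktrans")
  res2 <- paired_t_per_group(tab[sample(nrow(tab)), ], "ktrans")
  expect_equal(res1, res2)
  tab0 <- tab
  tab0$d_abs_ktrans <- 0
  res0 <- paired_t_per_group(tab0, "ktrans")
  expect_true(all(res0$zero_variance))
  expect_true(all(is.na(res0$t)))
})

test_that("two-group toy ANOVA matches a from-scratch sums-of-squares oracle", {
  rows <- list()
  vals <- list(`2` = c(0, 1, 2), `12` = c(1, 2, 3))
  for (h in c(2, 12)) for (i in 1:3)
    rows[[length(rows) + 1]] <- data.frame(
      animal_id = paste(h, i), group_h = h, n_roi = 1, excluded = FALSE,
      reason = "", d_abs_ktrans = vals[[as.character(h)]][i])
  tab <- cohort_table(rows)
  res <- anova_with_contrast(tab, "ktrans",
                             contrast = list(plus = 2, minus = 12))
  expect_equal(res$contrast$estimate, -1)
  # oracle: SS decomposition by hand
  d <- unlist(vals); g <- rep(c(2, 12), each = 3)
  ss_tot <- sum((d - mean(d))^2)
  ss_b <- sum(tapply(d, g, function(x) length(x) * (mean(x) - mean(d))^2))
  ss_w <- ss_tot - ss_b
  f_oracle <- (ss_b / 1) / (ss_w / 4)
  expect_equal(res$anova$f, f_oracle, tolerance = 1e-12)
  expect_equal(res$anova$p_overall, pf(f_oracle, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$anova$ss_total, ss_tot, tolerance = 1e-12)
})

test_that("equal group means give a zero contrast estimate", {
  rows <- list()
  for (h in c(2, 4, 8, 12, 24)) for (i in 1:3)
    rows[[length(rows) + 1]] <- data.frame(
      animal_id = paste(h, i), group_h = h, n_roi = 1, excluded = FALSE,
      reason = "", d_abs_ktrans = c(-1, 0, 1)[i] + 5)
  tab <- cohort_table(rows)
  res <- anova_with_contrast(tab, "ktrans")
  expect_equal(res$contrast$estimate, 0, tolerance = 1e-12)
})

test_that("ANOVA SS decomposition and contrast internal consistency hold", {
  tab <- toy_table()
  res <- anova_with_contrast(tab, "ktrans")
  expect_equal(res$anova$ss_total,
               res$anova$ss_between + res$anova$ss_within,
               tolerance = 1e-10 * res$anova$ss_total)
  # contrast p equals the two-sided t p-value from its SE and MSE df
  p_from_t <- 2 * pt(-abs(res$contrast$t), res$contrast$df)
  expect_equal(res$contrast$p, p_from_t, tolerance = 1e-14)
  # contrast estimate equals pooled-animal mean difference
  d <- tab$d_abs_ktrans
  est_oracle <- mean(d[tab$group_h %in% c(2, 4)]) -
    mean(d[tab$group_h %in% c(12, 24)])
  expect_equal(res$contrast$estimate, est_oracle, tolerance = 1e-12)
})

test_that("boxplot summary of {1..5} gives median 3 and IQR [2, 4]", {
  rows <- lapply(1:5, function(i)
    data.frame(animal_id = i, group_h = 8, n_roi = 1, excluded = FALSE,
               reason = "", d_pct_ktrans = i))
  bp <- export_boxplot_data(cohort_table(rows), "ktrans", "percent")
  expect_equal(bp$stats$median, 3)
  expect_equal(bp$stats$q1, 2)
  expect_equal(bp$stats$q3, 4)
  expect_equal(nrow(bp$outliers), 0)
})

test_that("boxplot quartiles match a sort-based oracle on random tables", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(5:12, 1)
    vals <- rnorm(n)
    rows <- lapply(seq_len(n), function(i)
      data.frame(animal_id = i, group_h = 8, n_roi = 1, excluded = FALSE,
                 reason = "", d_pct_ktrans = vals[i]))
    bp <- export_boxplot_data(cohort_table(rows), "ktrans", "percent")
    s <- sort(vals)
    expect_equal(bp$stats$median, median(s), tolerance = 1e-12)
    expect_equal(bp$stats$q1, unname(quantile(s, 0.25)), tolerance = 1e-12)
    expect_equal(bp$stats$q3, unname(quantile(s, 0.75)), tolerance = 1e-12)
    iqr <- bp$stats$q3 - bp$stats$q1
    expect_equal(bp$stats$whisker_lo, min(s[s >= bp$stats$q1 - 1.5 * iqr]))
    expect_equal(bp$stats$whisker_hi, max(s[s <= bp$stats$q3 + 1.5 * iqr]))
  }
})

test_that("sign structure of pooled differences is recovered across cohorts", {
  d <- cohort_design()
  set.seed(44)
  ok <- replicate(100, {
    s <- draw_cohort_shifts(d)
    mean(s$d_ktrans[s$group_h %in% c(2, 4)]) > 0 &&
      mean(s$d_ktrans[s$group_h %in% c(12, 24)]) < 0
  })
  expect_gte(mean(ok), 0.95)
})

test_that("an injected Ktrans shift is recovered through the full pipeline", {
  # one animal, fixed shift +0.0050, SNR 30: recovered absolute difference
  # should land within +/- 0.0010 of the injected value
  st <- default_shift_table()
  st[, grep("_mean$|_sd$", names(st))] <- 0
  st$ktrans_mean <- 0.0050
  d <- cohort_design(group_hours = 2, group_sizes = 1L,
                     shift_table = st[st$group_h == 2, ])
  spec <- acq_spec()
  aif <- make_aif(spec)
  set.seed(52)
  tr <- make_ground_truth(d, spec)
  sdn <- noise_sd_for_snr(spec, 30)
  pair <- list(animal_id = "A01", group_h = 2)
  for (s in c("test", "retest")) {
    study <- synthesize_signals(tr[[1]][[s]], aif, spec, noise_sd = sdn)
    pair[[s]] <- suppressWarnings(process_study(study))$maps
  }
  row <- summarize_roi(pair)
  expect_false(row$excluded)
  expect_lt(abs(row$d_abs_ktrans - 0.0050), 0.0010)
})
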