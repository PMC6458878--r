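# Mixed-model time analysis: df bookkeeping, contrasts, effect sizes,
# Tukey adjustment, correlations, BH and within-subject error bars.

test_that("residual df reproduce the design bookkeeping exactly", {
  tab4 <- fixture_table(n = 24, shifts = c(0, -3, -2, -2))
  fit4 <- fit_timecourse(tab4, "y")
  expect_equal(fit4$df_resid, 69)          # 96 - 24 - 3
  expect_equal(fit4$anova$df, 3)
  ct4 <- apriori_contrasts(fit4, direction = "decrease")
  expect_equal(ct4$df, rep(69, 3))

  tab3 <- fixture_table(n = 24, shifts = c(0, 0.5, 0.2))
  fit3 <- fit_timecourse(tab3, "y")
  expect_equal(fit3$df_resid, 46)          # 72 - 24 - 2
  ct3 <- apriori_contrasts(fit3, direction = "increase")
  expect_equal(ct3$df, rep(46, 2))
  expect_equal(fit3$anova$df, 2)
})

test_that("unbalanced tables are rejected", {
  tab <- fixture_table(n = 6)
  expect_error(fit_timecourse(tab[-1, ], "y"), "unbalanced")
})

test_that("a constant outcome shows no time effect", {
  tab <- fixture_table(n = 8, sd_sub = 0, sd_res = 0)
  tab$value <- 5
  a <- fit_time_anova(tab, "y")
  expect_equal(a$chi_sq, 0)
  expect_equal(a$p, 1)
})

test_that("the null LRT stays near zero and effects are detected", {
  tab <- fixture_table(n = 24, shifts = c(0, -5, -5, -5), sd_res = 2,
                       seed = 3)
  a <- fit_time_anova(tab, "y")
  expect_lt(a$p, 0.001)
})

test_that("one-tailed Bonferroni p values follow the observed-tail convention", {
  for (s in 1:5) {
    tab <- fixture_table(n = 12, shifts = c(0, -1, 0.5, 0), seed = s)
    fit <- fit_timecourse(tab, "y")
    ct <- apriori_contrasts(fit, direction = "decrease")
    m <- nrow(ct)
    expect_equal(ct$p_one_tailed_bonf,
                 pmin(1, m * pt(-abs(ct$t), ct$df)))
    expect_true(all(ct$p_one_tailed_bonf <= 1))
  }
  expect_error(apriori_contrasts(fit_timecourse(
    fixture_table(n = 6), "y")), "direction")
})

test_that("effect size r conversion is monotone and bounded", {
  expect_equal(effect_size_r(0, 69), 0)
  r_seq <- effect_size_r(c(0.5, 1, 2, 4, 8), 46)
  expect_true(all(diff(r_seq) > 0))
  expect_true(all(r_seq >= 0 & r_seq < 1))
  # decreasing in df at fixed |t|
  expect_gt(effect_size_r(2, 10), effect_size_r(2, 100))
  # symmetric in the sign of t
  expect_equal(effect_size_r(-2.76, 69), effect_size_r(2.76, 69))
  expect_error(effect_size_r(1, 0), "df")
})

test_that("the baseline-vs-follow-up contrast has zero-sum weights and a null at equality", {
  # construct data where t1 equals the mean of t2..t4 for every subject
  n <- 16
  set.seed(4)
  b <- rnorm(n, 20, 5); d <- rnorm(n, 0, 3)
  tab <- data.frame(
    subject = rep(sprintf("S%02d", 1:n), each = 4),
    timepoint = rep(paste0("t", 1:4), n),
    outcome = "y",
    value = as.vector(rbind(b, b + d, b - d, b)))
  res <- mean_followup_contrast(tab, "y")
  w <- attr(res, "weights")
  expect_equal(sum(w), 0)
  expect_equal(w, c(1, -1/3, -1/3, -1/3))
  expect_lt(abs(res$t), 1e-8)
  expect_equal(res$df, 4 * n - n - 3)
})

test_that("the follow-up contrast tracks an injected distress decrease", {
  hits <- vapply(1:40, function(s) {
    tab <- fixture_table(n = 24, shifts = c(0, -2.5, -2.5, -2.5),
                         sd_res = 5, seed = s)
    mean_followup_contrast(tab, "y")$t < 0
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("Tukey post hoc compares all pairs with single-step adjustment", {
  tab <- fixture_table(n = 24, shifts = c(0, -4, -1, 0), sd_res = 3, seed = 2)
  fit <- fit_timecourse(tab, "y")
  tk <- tukey_posthoc(fit)
  expect_equal(nrow(tk), 6)                      # 4 * 3 / 2
  expect_true(all(tk$p_adjusted >= tk$p_unadjusted - 1e-12))
  expect_setequal(tk$label, c("t1-t2", "t1-t3", "t1-t4", "t2-t3",
                              "t2-t4", "t3-t4"))
  # with two timepoints the single-step family collapses to the plain test
  tab2 <- fixture_table(n = 20, shifts = c(0, -2), sd_res = 4, seed = 5)
  tk2 <- tukey_posthoc(fit_timecourse(tab2, "y"))
  expect_equal(nrow(tk2), 1)
  expect_lt(abs(tk2$p_adjusted - tk2$p_unadjusted), 1e-6)
})

test_that("difference-score correlations report r(n-2) with one-tailed p", {
  x <- seq_len(24)
  res <- diff_corr(-2 * x, x, alternative = "less")
  expect_equal(res$r, -1)
  expect_equal(res$label, "r(22)")
  expect_lt(res$p, 1e-10)
  expect_error(diff_corr(1:2, 1:2), "3 complete")
  # estimated r concentrates on the generating correlation
  set.seed(9)
  r_hat <- vapply(1:100, function(i) {
    z <- rnorm(24)
    x <- z + rnorm(24, 0, 0.8)
    y <- -z + rnorm(24, 0, 0.8)
    diff_corr(x, y)$r
  }, 0)
  rho <- -1 / (1 + 0.8^2)
  expect_lt(abs(mean(r_hat) - rho), 0.1)
})

test_that("BH adjustment matches the brute-force step-up rule", {
  step_up <- function(p) {                      # independent oracle
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(4:8, 1))
    expect_equal(bh_adjust(p), step_up(p))
  }
})

test_that("Morey within-subject SEs remove subject offsets and apply sqrt(T/(T-1))", {
  tab <- fixture_table(n = 20, shifts = c(0, -2, -1, 0), sd_sub = 0,
                       sd_res = 3, seed = 7)
  se <- morey_within_se(tab, "y")
  # with no between-subject variance the correction factor is visible directly
  man <- vapply(paste0("t", 1:4), function(tp) {
    v <- tab$value[tab$timepoint == tp]
    sub_m <- tapply(tab$value, tab$subject, mean)
    cv <- v - sub_m[tab$subject[tab$timepoint == tp]] + mean(tab$value)
    sd(cv) / sqrt(length(cv))
  }, 0)
  expect_equal(unname(se), unname(man) * sqrt(4 / 3))
  # additive subject offsets leave the error bars unchanged
  tab2 <- tab
  off <- rnorm(20, 0, 50)
  names(off) <- sprintf("S%02d", 1:20)
  tab2$value <- tab2$value + off[tab2$subject]
  expect_equal(morey_within_se(tab2, "y"), se)
})

test_that("the age median split assigns ties to the young group", {
  tab <- fixture_table(n = 4)
  ages <- c(S01 = 30, S02 = 40, S03 = 50, S04 = 60)
  res <- age_median_split_control(tab, ages, "y")
  expect_equal(res$median, 45)
  expect_equal(unname(res$group_sizes["young"]), 2L)
  expect_equal(unname(res$group_sizes["old"]), 2L)
  # a median-aged subject lands in the young group
  ages2 <- c(S01 = 30, S02 = 44, S03 = 44, S04 = 60)
  res2 <- age_median_split_control(tab, ages2, "y")
  expect_equal(unname(res2$group_sizes["young"]), 3L)
})

test_that("the age interaction model has the expected df and a calibrated null", {
  tab <- fixture_table(n = 24, shifts = c(0, -2, -1, 0), seed = 3)
  ages <- setNames(runif(24, 24, 71), sprintf("S%02d", 1:24))
  res <- age_median_split_control(tab, ages, "y")
  expect_equal(res$df, 4)                       # group + time x group
  tab3 <- fixture_table(n = 24, shifts = c(0, 1, 2), seed = 4)
  expect_equal(age_median_split_control(tab3, ages, "y")$df, 3)
  # no interaction injected: mostly non-significant over seeded runs
  sig <- vapply(1:20, function(s) {
    tb <- fixture_table(n = 24, shifts = c(0, -2, -1, 0), seed = 100 + s)
    ag <- setNames(runif(24, 24, 71), sprintf("S%02d", 1:24))
    age_median_split_control(tb, ag, "y")$p < 0.05
  }, TRUE)
  expect_gte(mean(!sig), 0.9)
})
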