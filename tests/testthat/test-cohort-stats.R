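test_that("time bins partition the positive axis with the 4-day edge in
           the second bin", {
  expect_identical(as.character(assignTimeBin(12)), "<=96h")
  expect_identical(as.character(assignTimeBin(4 * 24)), "4-7d")  # 96 h
  expect_identical(as.character(assignTimeBin(7 * 24)), "4-7d")  # 168 h
  expect_identical(as.character(assignTimeBin(169)), "8-21d")
  expect_identical(as.character(assignTimeBin(21 * 24)), "8-21d")
  expect_identical(as.character(assignTimeBin(34 * 24)), ">=22d")
  expect_error(assignTimeBin(0), "positive")
  expect_error(assignTimeBin(-5), "positive")
  # every positive time lands in exactly one bin
  set.seed(2)
  t_h <- exp(runif(500, log(0.5), log(2000)))
  bins <- assignTimeBin(t_h)
  expect_false(anyNA(bins))
  expect_identical(levels(bins), c("<=96h", "4-7d", "8-21d", ">=22d"))
})

test_that("Pearson correlation matches the covariance-formula oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8, 12.2)
  res <- pearsonCor(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_manual <- r_manual * sqrt((6 - 2) / (1 - r_manual^2))
  expect_lt(abs(res$estimate - r_manual), 1e-12)
  expect_lt(abs(res$p_value - 2 * pt(-abs(t_manual), 4)), 1e-12)

  expect_equal(pearsonCor(x, 2 * x + 1)$estimate, 1, tolerance = 1e-12)
  expect_equal(pearsonCor(x, -x)$estimate, -1, tolerance = 1e-12)
  expect_error(pearsonCor(x, rep(1, 6)), "zero variance")
  expect_error(pearsonCor(1:2, 1:2), "at least 3")
})

test_that("one-way ANOVA with LSD matches brute-force sums of squares", {
  g <- list(a = c(1.1, 2.3, 1.9, 2.8), b = c(3.0, 3.4, 2.6),
            c = c(4.1, 5.2, 4.4, 4.9, 5.0))
  res <- anovaLSD(g)
  v <- unlist(g); gi <- rep(names(g), lengths(g))
  grand <- mean(v)
  ss_b <- sum(tapply(v, gi, function(x) length(x) * (mean(x) - grand)^2))
  ss_w <- sum(tapply(v, gi, function(x) sum((x - mean(x))^2)))
  df_b <- 2; df_w <- length(v) - 3
  f_manual <- (ss_b / df_b) / (ss_w / df_w)
  expect_lt(abs(res$statistic - f_manual), 1e-10)
  expect_lt(abs(res$p_value - pf(f_manual, df_b, df_w, lower.tail = FALSE)),
            1e-10)
  # LSD pairwise: pooled-MSE t, no adjustment
  mse <- ss_w / df_w
  t_ab <- (mean(g$a) - mean(g$b)) / sqrt(mse * (1 / 4 + 1 / 3))
  p_ab <- 2 * pt(-abs(t_ab), df_w)
  row <- res$pairwise[res$pairwise$group1 == "a" &
                        res$pairwise$group2 == "b", ]
  expect_lt(abs(row$t - t_ab), 1e-10)
  expect_lt(abs(row$p - p_ab), 1e-10)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  a <- c(1.2, 0.8, 1.5, 1.1); b <- c(2.2, 1.9, 2.6, 2.4, 2.1)
  f_res <- anovaLSD(list(a = a, b = b))
  t_res <- ttestInd(a, b)
  expect_lt(abs(f_res$statistic - t_res$statistic^2), 1e-10)
  expect_lt(abs(f_res$p_value - t_res$p_value), 1e-10)
})

test_that("ANOVA edge cases behave as specified", {
  expect_error(anovaLSD(list(a = c(1, 1), b = c(1, 1))), "identical")
  eq <- anovaLSD(list(a = c(1, 2, 3), b = c(2, 1, 3), c = c(3, 2, 1)))
  expect_lt(eq$statistic, 1e-10)
  expect_gt(eq$p_value, 0.999)
  # groups with n < 2 are reported but excluded from the model
  res <- anovaLSD(list(a = c(1, 2, 3), b = c(2, 3, 4), tiny = 5))
  expect_identical(unname(res$group_ns["tiny"]), 1L)
  expect_identical(res$df[2], 4L)         # residual df from a and b only
  expect_error(anovaLSD(list(a = 1:3, b = 2)), "at least 2 groups")
})

test_that("the independent-samples t-test matches the pooled formula", {
  a <- c(1.3, 2.1, 1.7, 2.4); b <- c(2.9, 3.3, 2.5, 3.8)
  res <- ttestInd(a, b)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_lt(abs(res$statistic - t_manual), 1e-12)
  expect_lt(abs(res$p_value - 2 * pt(-abs(t_manual), 6)), 1e-12)

  swap <- ttestInd(b, a)                   # antisymmetry
  expect_equal(swap$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(swap$p_value, res$p_value, tolerance = 1e-12)

  same <- ttestInd(c(1, 1, 1), c(1, 1))    # degenerate: identical data
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  expect_error(ttestInd(c(1, 1), c(2, 2)), "zero variance")
  expect_error(ttestInd(1, 1:3), "at least 2")

  welch <- ttestInd(a, c(b, 10), var_equal = FALSE)
  expect_lt(abs(welch$p_value -
                  t.test(a, c(b, 10))$p.value), 1e-12)
})

test_that("onset-time bins of the bundled cohort give the published group
           sizes", {
  co <- cohortFromDemographics(followup = NULL)
  bins <- assignTimeBin(co$onset_time_h)
  expect_identical(as.integer(table(bins)), c(30L, 13L, 0L, 0L))
})

test_that("cohort tables are summarized with the published structure", {
  set.seed(31)
  co <- cohortFromDemographics(ineffective_ids = c(28L, 2L))
  n <- nrow(co)
  co$lesion_aptw_pct <- rnorm(n, -0.5, 0.8)
  co$cnawm_aptw_pct <- rnorm(n, 0.35, 0.4)
  co$contrast_pct <- co$lesion_aptw_pct - co$cnawm_aptw_pct
  co$nihss <- pmax(0, round(rnorm(n, 4, 2)))

  tabs <- buildCohortTables(co)
  t2 <- tabs$by_post_treatment
  expect_identical(t2$n[t2$measure == "lesion_aptw_pct" &
                          t2$group == "pre"], 43L)
  # ineffective patients' post scans are excluded everywhere
  expect_identical(sum(t2$n[t2$measure == "lesion_aptw_pct"]), 43L + 42L)
  expect_true(all(tabs$correlations$subset %in% c("untreated", "treated")))

  # pre == post: comparisons cannot reject equality
  co2 <- co[co$phase == "pre", ]
  post2 <- co2
  post2$phase <- "post"; post2$treated <- TRUE; post2$effective <- TRUE
  post2$scan_id <- paste0(post2$scan_id, "b")
  post2$post_treatment_time_h <- 48
  both <- rbind(co2, post2)
  t3 <- buildCohortTables(both)$by_onset
  row <- t3[t3$onset_bin == "<=96h" & t3$measure == "lesion_aptw_pct", ]
  expect_equal(row$mean_pre, row$mean_post, tolerance = 1e-12)
  expect_gt(row$p, 0.999)
})

test_that("simulated cohorts attain the target NIHSS linkage on average", {
  rs <- vapply(1:50, function(s)
    pearsonCor(simulateCohort(n = 43, target_r = -0.491,
                              seed = 100 + s)$lesion_aptw_pct,
               simulateCohort(n = 43, target_r = -0.491,
                              seed = 100 + s)$nihss)$estimate,
    numeric(1))
  # Monte-Carlo error of the mean of 50 sample correlations ~ 0.017;
  # integer rounding and clamping of NIHSS attenuates |r| slightly
  expect_lt(abs(mean(rs) + 0.491), 0.06)
})
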