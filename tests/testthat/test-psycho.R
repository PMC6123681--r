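# Psychometric curves, sensitivity extraction, and polarity statistics.

make_trials <- function(n, contrast, correct = TRUE, rt = 0.3,
                        prompted = FALSE, subject = 1, speed = 3) {
  data.frame(subject_id = subject, speed = speed,
             contrast = rep_len(contrast, n),
             true_direction = "left",
             choice = ifelse(rep_len(correct, n), "left", "right"),
             correct = rep_len(correct, n),
             rt = rep_len(rt, n), prompted = rep_len(prompted, n))
}

test_that("accuracy curves partition trials and include prompted ones", {
  set.seed(17)
  tr <- make_trials(400, contrast = runif(400, 0.01, 0.2))
  tr$prompted[1:50] <- TRUE
  curve <- build_accuracy_curve(tr, "light", n_bins = 8)
  expect_equal(sum(curve$n_per_bin), 400)
  expect_true(all(curve$values == 1))
  expect_true(all(diff(curve$bin_centers) > 0))

  # random 50/50 choices hover at chance
  tr2 <- make_trials(4000, contrast = runif(4000, 0.01, 0.2),
                     correct = sample(c(TRUE, FALSE), 4000, replace = TRUE))
  curve2 <- build_accuracy_curve(tr2, "light", n_bins = 4)
  expect_true(all(abs(curve2$values - 0.5) < 4 * sqrt(0.25 / 1000)))

  # polarity selection by contrast sign
  expect_error(build_accuracy_curve(tr, "dark"),
               class = "onoffmotion_empty_curve")
})

test_that("RT curves exclude prompted trials and follow the generator's monotonicity", {
  set.seed(19)
  c <- runif(600, 0.01, 0.2)
  tr <- make_trials(600, contrast = c, rt = 0.3)
  curve <- build_rt_curve(tr, "light", n_bins = 6)
  expect_true(all(curve$values == 0.3))

  # prompted-only input has nothing to bin
  tr_p <- make_trials(50, contrast = 0.1, prompted = TRUE, rt = NA)
  expect_error(build_rt_curve(tr_p, "light"),
               class = "onoffmotion_empty_curve")

  # RT decreasing in contrast by construction gives decreasing bin means
  tr2 <- make_trials(600, contrast = c, rt = 0.6 - 1.5 * c)
  curve2 <- build_rt_curve(tr2, "light", n_bins = 6)
  expect_true(all(diff(curve2$values) < 0))

  # removing prompted trials changes no RT output, only accuracy denominators
  tr3 <- make_trials(600, contrast = c, rt = 0.6 - 1.5 * c)
  tr3$prompted[1:100] <- TRUE
  tr3$rt[1:100] <- NA
  kept <- tr3[!tr3$prompted, ]
  c_all <- build_rt_curve(tr3, "light", n_bins = 6)
  c_kept <- build_rt_curve(kept, "light", n_bins = 6)
  expect_equal(c_all$values, c_kept$values)
  expect_equal(c_all$n_per_bin, c_kept$n_per_bin)
  a_all <- build_accuracy_curve(tr3, "light", n_bins = 6)
  a_kept <- build_accuracy_curve(kept, "light", n_bins = 6)
  expect_equal(sum(a_all$n_per_bin) - sum(a_kept$n_per_bin), 100)
})

test_that("sensitivity extraction inverts closed-form curves", {
  # linear accuracy: PC(c) = 0.5 + 5c on [0, 0.1] crosses 0.75 at c = 0.05
  c <- seq(0.001, 0.1, length.out = 60)
  acc <- psychometric_curve(c, 0.5 + 5 * c, rep(100, 60), "light", "accuracy")
  s <- sensitivity_from_accuracy(acc)
  expect_equal(s$threshold_contrast, 0.05, tolerance = 0.01 * 0.05)
  expect_equal(s$sensitivity, 20, tolerance = 0.01 * 20)
  expect_equal(s$sensitivity * s$threshold_contrast, 1)

  # floor above the criterion has no threshold
  high <- psychometric_curve(c, rep(0.9, 60), rep(100, 60), "light", "accuracy")
  expect_error(sensitivity_from_accuracy(high),
               class = "onoffmotion_no_threshold")

  # exponential RT: 300 + 200 exp(-c / 0.05) ms crosses halfway (400 ms)
  # at c = 0.05 log(2); sample widely enough that the curve attains its
  # extremes, since the halfway level is defined from the observed curve
  cr <- exp(seq(log(1e-4), log(0.6), length.out = 60))
  rt <- psychometric_curve(cr, 0.3 + 0.2 * exp(-cr / 0.05), rep(50, 60),
                           "dark", "rt")
  s2 <- sensitivity_from_rt(rt)
  expect_equal(s2$threshold_contrast, 0.05 * log(2), tolerance = 0.01)
  expect_equal(s2$sensitivity, 1 / (0.05 * log(2)), tolerance = 0.01)

  # flat RT curve has no halfway criterion
  flat <- psychometric_curve(cr, rep(0.4, 60), rep(50, 60), "dark", "rt")
  expect_error(sensitivity_from_rt(flat), class = "onoffmotion_no_threshold")

  # adding a constant to all RTs leaves the threshold contrast unchanged
  rt_shift <- psychometric_curve(cr, 0.5 + 0.2 * exp(-cr / 0.05), rep(50, 60),
                                 "dark", "rt")
  expect_equal(sensitivity_from_rt(rt_shift)$threshold_contrast,
               s2$threshold_contrast)
})

test_that("sensitivity scales inversely with the contrast axis", {
  c <- seq(0.001, 0.1, length.out = 60)
  acc <- psychometric_curve(c, 0.5 + 5 * c, rep(100, 60), "light", "accuracy")
  acc_k <- psychometric_curve(2 * c, 0.5 + 5 * c, rep(100, 60), "light",
                              "accuracy")
  expect_equal(sensitivity_from_accuracy(acc_k)$sensitivity,
               sensitivity_from_accuracy(acc)$sensitivity / 2)
})

test_that("the polarity ANOVA is symmetric under label swap and detects real effects", {
  spec <- observer_spec(n_subjects = 6, speeds = 3, c50_light = 0.02,
                        c50_dark = 0.05, seed = 314)
  tr <- generate_trial_table(spec, n_trials_per_subject = 400)
  tab <- binned_by_subject(tr, "accuracy", n_bins = 5)
  a <- polarity_anova(tab, "accuracy")
  expect_lt(a$p, 0.001)
  expect_equal(a$df1, 1)

  # swapping polarity labels leaves the F statistic unchanged
  swapped <- tab
  swapped$polarity <- ifelse(tab$polarity == "light", "dark", "light")
  a2 <- polarity_anova(swapped, "accuracy")
  expect_equal(a2$F, a$F)
  expect_equal(a2$p, a$p)

  # a collinear design is named, not silently dropped
  degenerate <- tab
  degenerate$contrast <- 1
  expect_error(polarity_anova(degenerate, "accuracy"),
               class = "onoffmotion_design_error")
})

test_that("the paired polarity test handles degenerate and regular cases", {
  x <- c(0.8, 0.7, 0.9, 0.85)
  same <- paired_polarity_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  const <- paired_polarity_test(x + 0.1, x)
  expect_true(const$degenerate)
  expect_equal(const$t, Inf)
  expect_equal(const$p, 0)

  set.seed(8)
  l <- rnorm(10, 0.8, 0.05)
  d <- rnorm(10, 0.7, 0.05)
  res <- paired_polarity_test(l, d)
  expect_equal(res$df, 9)
  expect_equal(res$p, stats::t.test(l - d)$p.value)

  expect_error(paired_polarity_test(1, 2),
               class = "onoffmotion_insufficient_data")
})

test_that("the trial-table analysis recovers the generator's sensitivity ordering", {
  spec <- observer_spec(n_subjects = 4, speeds = c(1, 30), seed = 2718)
  tr <- generate_trial_table(spec, n_trials_per_subject = 1500)
  res <- analyze_psycho(tr, n_bins = 10)
  acc <- res$sensitivity[res$sensitivity$criterion == "PC_075", ]
  s_light_1 <- acc$sensitivity[acc$speed == 1 & acc$polarity == "light"]
  s_dark_1 <- acc$sensitivity[acc$speed == 1 & acc$polarity == "dark"]
  # lights are more detectable at the low speed, by roughly c50_dark/c50_light
  expect_gt(s_light_1, s_dark_1)
  expect_equal(s_light_1 / s_dark_1, 0.032 / 0.020, tolerance = 0.2)
  # the light advantage shrinks at the high speed
  s_light_30 <- acc$sensitivity[acc$speed == 30 & acc$polarity == "light"]
  s_dark_30 <- acc$sensitivity[acc$speed == 30 & acc$polarity == "dark"]
  expect_lt(s_light_30 / s_dark_30, s_light_1 / s_dark_1)
})
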