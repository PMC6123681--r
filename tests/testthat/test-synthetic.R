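# Synthetic spike-event and trial-table generators.

test_that("spike generation is bit-reproducible under a fixed seed", {
  spec <- site_population_spec(n_sites = 3, speeds = c(5, 30),
                               true_latency_difference = c(`5` = 0.02, `30` = 0),
                               seed = 77)
  a <- generate_spike_tables(spec)
  b <- generate_spike_tables(spec)
  expect_identical(a, b)
  expect_setequal(names(a), c("site_id", "direction", "polarity", "speed",
                              "sweep_index", "spike_time"))
  # spike times respect the sweep window
  dur <- 40 / a$speed
  expect_true(all(a$spike_time >= 0 & a$spike_time <= dur))
  expect_true(all(a$sweep_index %in% 1:4))
})

test_that("a silent population yields an empty spike table", {
  spec <- site_population_spec(n_sites = 2, speeds = 5,
                               true_latency_difference = c(`5` = 0.01),
                               baseline_rate = 0,
                               pathway = pathway_params(1e-9, 0.4, 1.4, "ON"),
                               seed = 5)
  tab <- generate_spike_tables(spec)
  expect_equal(nrow(tab), 0)
  expect_setequal(names(tab), c("site_id", "direction", "polarity", "speed",
                                "sweep_index", "spike_time"))
})

test_that("spike counts match the rate integral within Poisson error", {
  spec <- site_population_spec(n_sites = 2, speeds = 5,
                               true_latency_difference = c(`5` = 0.015),
                               n_sweeps = 500, peak_time_jitter = 0,
                               n_directions = 4, seed = 13)
  tab <- generate_spike_tables(spec)
  gt <- attr(tab, "ground_truth")
  tmpl <- site_rate_templates(spec, 5, 0.015)
  dt <- tmpl$times[2] - tmpl$times[1]
  for (i in 1:2) {
    # direction gain is 1 at the preferred direction by construction
    rate <- tmpl$light
    expected <- sum(rate) * dt * 500
    observed <- sum(tab$site_id == i & tab$polarity == "light" &
                      tab$direction == gt$preferred_direction[i])
    expect_lt(abs(observed - expected), 3 * sqrt(expected))
  }
})

test_that("the noiseless templates encode the requested latency difference", {
  spec <- site_population_spec(n_sites = 2, speeds = 5,
                               true_latency_difference = c(`5` = 0.015),
                               seed = 1)
  tmpl <- site_rate_templates(spec, 5, 0.015)
  # the measured difference on binned, smoothed traces (the pipeline's
  # resolution) equals the target: rebuild that measurement here
  n_bins <- 35
  bm <- function(v) colMeans(matrix(v, nrow = length(v) / n_bins))
  lb <- smooth_rates(bm(tmpl$light))
  db <- smooth_rates(bm(tmpl$dark))
  tc <- (1:n_bins - 0.5) * tmpl$duration / n_bins
  phases <- ((1:8) - 0.5) / 8 * tmpl$duration / n_bins
  avg_l <- align_and_average(rep(list(lb), 8), phases, tc)
  avg_d <- align_and_average(rep(list(db), 8), phases, tc)
  expect_lt(abs(latency_difference(avg_l, avg_d)$difference - 0.015), 1e-4)
  # dark is the stronger response by 1/amplitude_ratio (up to grid phase)
  expect_equal(max(tmpl$dark - spec$baseline_rate),
               max(tmpl$light - spec$baseline_rate) / 0.8, tolerance = 1e-4)
})

test_that("trial generation is reproducible, consistent, and censored correctly", {
  spec <- observer_spec(n_subjects = 3, speeds = c(1, 10), seed = 55)
  a <- generate_trial_table(spec, n_trials_per_subject = 200)
  b <- generate_trial_table(spec, n_trials_per_subject = 200)
  expect_identical(a, b)
  expect_equal(nrow(a), 3 * 2 * 200)
  # correctness is choice == true_direction
  expect_equal(a$correct, a$choice == a$true_direction)
  # prompted trials carry no reaction time; unprompted ones beat the deadline
  expect_true(all(is.na(a$rt[a$prompted])))
  expect_true(all(a$rt[!a$prompted] <= 1))
  expect_error(generate_trial_table(spec, 0),
               class = "onoffmotion_invalid_parameter")
})

test_that("accuracy sits near 75% at c50 and saturates at high contrast", {
  spec <- observer_spec(n_subjects = 1, speeds = 3, c50_light = 0.03,
                        c50_dark = 0.03, lapse = 0, contrast_sd = 0.05,
                        seed = 404)
  tr <- generate_trial_table(spec, n_trials_per_subject = 60000)
  cm <- abs(tr$contrast)
  near <- cm > 0.028 & cm < 0.032
  p_hat <- mean(tr$correct[near])
  expect_equal(p_hat, 0.75, tolerance = 3 * sqrt(0.25 / sum(near)) / 0.75)
  high <- cm > 0.12
  expect_gt(mean(tr$correct[high]), 0.97)
})
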