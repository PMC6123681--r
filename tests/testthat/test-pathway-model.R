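# Forward latency model: stimulus construction, the Naka-Rushton transform
# with a power threshold, and latency readout.

test_that("gaussian stimulus has FWHM = bar_width / speed and peaks at its center", {
  stim <- gaussian_stimulus(speed = 5, bar_width = 2.1, peak = 1)
  above_half <- stim$times[stim$values >= 0.5]
  fwhm <- max(above_half) - min(above_half)
  expect_equal(fwhm, 0.42, tolerance = 2 * stim$dt / 0.42)
  expect_equal(stim$values[which.min(abs(stim$times - stim$center))], 1)
  expect_equal(max(stim$values), 1)
  # symmetric about the center
  v <- stim$values
  expect_equal(v, rev(v))

  # doubling the speed halves the width
  stim2 <- gaussian_stimulus(speed = 10, bar_width = 2.1, dt = stim$dt)
  expect_equal(stim2$sigma / stim$sigma, 0.5)

  # window spans at least +-4 sigma
  expect_gte(stim$center - min(stim$times), 4 * stim$sigma)

  expect_error(gaussian_stimulus(-5), class = "onoffmotion_invalid_parameter")
  expect_error(gaussian_stimulus(5, bar_width = 0),
               class = "onoffmotion_invalid_parameter")
  expect_error(gaussian_stimulus(5, dt = -1e-3),
               class = "onoffmotion_invalid_parameter")
})

test_that("Naka-Rushton transform hits its half-saturation point and endpoints", {
  on <- on_pathway_defaults()
  off <- off_pathway_defaults()
  # constant drive at L50 with th = 1 gives Rmax / 2
  expect_equal(naka_rushton_response(rep(on$l_50, 10), on, th = 1),
               rep(on$r_max / 2, 10), tolerance = 1e-9)
  expect_equal(naka_rushton_response(off$l_50, off, th = 1), off$r_max / 2,
               tolerance = 1e-9)
  # zero drive gives zero response
  expect_equal(naka_rushton_response(0, on, th = 1), 0)
  # full drive with ON defaults: hand-calculated value
  expect_equal(naka_rushton_response(1, on, th = 1), 62.6346,
               tolerance = 1e-5)
  expect_equal(naka_rushton_response(1, on, th = 1),
               nr_scalar(1, 80, 0.4, 1.4))
  expect_error(naka_rushton_response(c(0.2, -0.1), on),
               class = "onoffmotion_invalid_input")
})

test_that("response is monotone in drive and th sharpens the response", {
  on <- on_pathway_defaults()
  set.seed(42)
  for (i in 1:10) {
    s <- sort(runif(50))
    r <- naka_rushton_response(s, on, th = 1)
    expect_true(all(diff(r) >= 0))
  }
  # larger th narrows the region above half of the response's own peak
  stim <- gaussian_stimulus(5)
  width_at_th <- function(th) {
    r <- naka_rushton_response(stim, on, th = th)
    sum(r$rates >= max(r$rates) / 2)
  }
  expect_lt(width_at_th(3), width_at_th(1))
})

test_that("ON defaults sit strictly below OFF defaults parameter-wise", {
  on <- on_pathway_defaults()
  off <- off_pathway_defaults()
  expect_lt(on$r_max, off$r_max)
  expect_lt(on$l_50, off$l_50)
  expect_lt(on$n, off$n)
  expect_true(all(diff(default_threshold_schedule()) >= 0))
})

test_that("latency readout matches the closed-form Gaussian inversion", {
  dt <- 1e-4
  times <- seq(0, 2, by = dt)
  sigma <- 0.15
  center <- 1
  resp <- list(times = times, rates = gauss_trace(times, 50, center, sigma))
  lat <- latency_at_half_reference(resp, 50)
  expect_equal(lat, gauss_rising_crossing(50, center, sigma, 25),
               tolerance = dt)

  # time-shift equivariance is exact: same samples, shifted time stamps
  shifted <- list(times = times + 0.123, rates = resp$rates)
  expect_equal(latency_at_half_reference(shifted, 50) - lat, 0.123)

  # amplitude-only asymmetry: dark = 1.25 x light, same shape, light's peak
  # as the reference: darks get faster by the closed-form amount
  dark <- list(times = times, rates = gauss_trace(times, 62.5, center, sigma))
  lat_dark <- latency_at_half_reference(dark, 50)
  expect_equal(lat_dark, gauss_rising_crossing(62.5, center, sigma, 25),
               tolerance = dt)
  expect_equal(lat_dark - lat,
               sigma * (sqrt(2 * log(2)) - sqrt(2 * log(2.5))),
               tolerance = 2 * dt)
  expect_lt(lat_dark, lat)

  # a response that never reaches the level signals no-crossing
  expect_error(latency_at_half_reference(resp, 150),
               class = "onoffmotion_no_crossing")
})

test_that("identical ON and OFF parameters give zero latency difference", {
  p <- pathway_params(90, 0.45, 1.8, "ON")
  p2 <- pathway_params(90, 0.45, 1.8, "OFF")
  sim <- simulate_latency_difference(p, p2, speeds = c(5, 30),
                                     schedule = c(`5` = 1.5, `30` = 3))
  expect_equal(sim$difference, c(0, 0))
})

test_that("printed defaults give lights the lead at 5 deg/s, darks at 60 deg/s", {
  sim <- simulate_latency_difference()
  expect_gt(sim$difference[sim$speed == 5], 0)
  expect_lte(sim$difference[sim$speed == 60], default_model_dt(60))
  # the drop from 5 to 10 deg/s is the sharp feature the threshold creates
  expect_lt(sim$difference[sim$speed == 10], 0.25 * sim$difference[sim$speed == 5])
})

test_that("without the threshold the difference decays monotonically toward zero", {
  sim <- simulate_latency_difference(th = 1)
  expect_true(all(sim$difference > 0))
  expect_true(all(diff(sim$difference) < 0))
  # scales with stimulus width: halving width halves the difference
  expect_equal(sim$difference[sim$speed == 60] / sim$difference[sim$speed == 30],
               0.5, tolerance = 0.05)
})

test_that("missing threshold entries are a configuration error", {
  expect_error(simulate_latency_difference(speeds = 7),
               class = "onoffmotion_config_error")
})

test_that("halving dt changes latency differences by less than dt", {
  for (speed in c(5, 30)) {
    dt <- default_model_dt(speed)
    d1 <- simulate_latency_difference(speeds = speed, dt = dt)$difference
    d2 <- simulate_latency_difference(speeds = speed, dt = dt / 2)$difference
    expect_lt(abs(d1 - d2), dt)
  }
})
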