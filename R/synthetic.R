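# Seeded generators for synthetic spike-event tables and 2AFC trial tables
# with the statistical structure the two analysis pipelines assume, so every
# stage can be exercised and validated without recordings.

#' Specification of a synthetic population of recording sites
#'
#' Describes a population of direction-selective cortical sites responding to
#' light and dark bars swept across the screen. Light responses are the
#' ON-pathway Naka-Rushton transform of a Gaussian stimulus time course; dark
#' responses share that shape, scaled up by `1 / amplitude_ratio` (darks are
#' stronger) and time-shifted so that the half-amplitude latency difference
#' of the noiseless binned-and-smoothed traces equals
#' `true_latency_difference` at each speed (see [site_rate_templates()]).
#' Defining the ground truth as the measurable half-amplitude difference
#' (rather than a raw shift) makes recovery well defined: a raw shift of x ms
#' would not produce a measured difference of x ms, because the stronger dark
#' trace crosses the light-referenced level relatively earlier.
#'
#' @param n_sites number of recording sites (>= 2).
#' @param speeds bar speeds, deg/s.
#' @param true_latency_difference dark-minus-light half-amplitude latency
#'   difference (s): scalar or named per speed.
#' @param amplitude_ratio light/dark peak-rate ratio in (0, 1\]; default 0.8
#'   (light responses 20% weaker).
#' @param dsi_mean,dsi_sd site-to-site distribution of the direction
#'   selectivity index (truncated to \[0.05, 0.95\]).
#' @param peak_time_jitter sd of the site-to-site response-peak offset (s),
#'   emulating receptive-field scatter.
#' @param n_sweeps stimulus repeats per condition (default 4).
#' @param baseline_rate spontaneous rate, spikes/s.
#' @param bar_width bar width, deg.
#' @param rf_width receptive-field width, deg; the response time course has
#'   FWHM `(bar_width + rf_width) / speed`.
#' @param screen_traverse bar travel distance, deg; sweep duration is
#'   `screen_traverse / speed`.
#' @param n_directions number of motion directions (default 16).
#' @param pathway [pathway_params()] giving the response shape (default: the
#'   ON defaults).
#' @param seed integer seed; all generator randomness flows from it.
#' @return an object of class `"site_population_spec"`.
#' @export
site_population_spec <- function(n_sites = 30,
                                 speeds = c(5, 10, 16.15, 30, 60),
                                 true_latency_difference = c(
                                   `5` = 0.025, `10` = 0.005, `16.15` = 0.002,
                                   `30` = 0, `60` = -0.002),
                                 amplitude_ratio = 0.8,
                                 dsi_mean = 0.6, dsi_sd = 0.15,
                                 peak_time_jitter = 0.2,
                                 n_sweeps = 4,
                                 baseline_rate = 2,
                                 bar_width = 2.1,
                                 rf_width = 4,
                                 screen_traverse = 40,
                                 n_directions = 16,
                                 pathway = on_pathway_defaults(),
                                 seed = 1) {
  if (n_sites < 2) {
    stop_onoff("`n_sites` must be at least 2", "onoffmotion_invalid_parameter")
  }
  if (amplitude_ratio <= 0 || amplitude_ratio > 1) {
    stop_onoff("`amplitude_ratio` must lie in (0, 1]",
               "onoffmotion_invalid_parameter")
  }
  if (peak_time_jitter < 0) {
    stop_onoff("`peak_time_jitter` must be non-negative",
               "onoffmotion_invalid_parameter")
  }
  if (length(true_latency_difference) == 1L && is.null(names(true_latency_difference))) {
    true_latency_difference <- stats::setNames(
      rep(true_latency_difference, length(speeds)), as.character(speeds))
  }
  missing <- setdiff(as.character(speeds), names(true_latency_difference))
  if (length(missing) > 0L) {
    stop_onoff(sprintf("no true latency difference for speed(s) %s",
                       paste(missing, collapse = ", ")),
               "onoffmotion_config_error")
  }
  structure(
    list(n_sites = n_sites, speeds = speeds,
         true_latency_difference = true_latency_difference,
         amplitude_ratio = amplitude_ratio,
         dsi_mean = dsi_mean, dsi_sd = dsi_sd,
         peak_time_jitter = peak_time_jitter, n_sweeps = n_sweeps,
         baseline_rate = baseline_rate, bar_width = bar_width,
         rf_width = rf_width, screen_traverse = screen_traverse,
         n_directions = n_directions, pathway = pathway, seed = seed),
    class = "site_population_spec"
  )
}

#' Noiseless light/dark rate templates for one site and speed
#'
#' Builds the preferred-direction light and dark rate functions on a fine
#' grid: light is the pathway's Naka-Rushton transform of the Gaussian
#' stimulus plus baseline; dark is the same shape scaled by
#' `1 / amplitude_ratio` and time-shifted. The shift is solved numerically so
#' that the half-amplitude latency difference *as the pipeline measures it* —
#' on 35-bin, Gaussian-smoothed traces — equals `delta`. Defining the ground
#' truth at the measurement resolution matters: binning at 35 bins and
#' smoothing with a 1-bin kernel displace the interpolated crossings by a
#' systematic amount that does not average away with more sweeps or sites, so
#' a shift solved on the continuous traces would not be recoverable.
#'
#' @param spec a [site_population_spec()].
#' @param speed bar speed, deg/s.
#' @param delta target half-amplitude latency difference (s) on the binned,
#'   smoothed noiseless traces.
#' @param center response-peak time, s (default mid-sweep).
#' @param n_bins,sigma_bins resolution at which the pipeline measures
#'   (defaults: 35 bins, smoothing sd 1 bin).
#' @return list with `times`, `light`, `dark`, `duration`, `shift`, `sigma`.
#' @export
site_rate_templates <- function(spec, speed, delta, center = NULL,
                                n_bins = 35, sigma_bins = 1) {
  duration <- spec$screen_traverse / speed
  if (is.null(center)) center <- duration / 2
  oversample <- 40L
  n_fine <- n_bins * oversample
  dt <- duration / n_fine
  times <- (seq_len(n_fine) - 0.5) * dt
  bin_centers <- (seq_len(n_bins) - 0.5) * (duration / n_bins)
  fwhm <- (spec$bar_width + spec$rf_width) / speed
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  resp_at <- function(offset) {
    stim <- exp(-(times - center - offset)^2 / (2 * sigma^2))
    naka_rushton_response(stim, spec$pathway, th = 1)
  }
  bin_means <- function(v) colMeans(matrix(v, nrow = oversample))
  light <- resp_at(0) + spec$baseline_rate
  light_b <- smooth_rates(bin_means(light), sigma_bins)
  # The pipeline measures the crossing difference after re-gridding each
  # site's binned, smoothed trace at an arbitrary sub-bin phase (the fitted
  # peak time). The measured difference varies with that phase, so the target
  # is the phase-averaged pipeline measurement: run the actual alignment /
  # averaging / crossing machinery over a uniform spread of phases.
  phases <- (seq_len(8L) - 0.5) / 8 * (duration / n_bins)
  measured_diff <- function(s) {
    dark <- resp_at(s) / spec$amplitude_ratio + spec$baseline_rate
    dark_b <- smooth_rates(bin_means(dark), sigma_bins)
    avg_l <- align_and_average(rep(list(light_b), length(phases)), phases,
                               bin_centers)
    avg_d <- align_and_average(rep(list(dark_b), length(phases)), phases,
                               bin_centers)
    latency_difference(avg_l, avg_d)$difference
  }
  # continuous-trace solution as the starting point, then solve at the
  # pipeline's resolution
  level0 <- max(light) / 2
  s0 <- delta - (first_rising_crossing(times, resp_at(0) / spec$amplitude_ratio +
                                         spec$baseline_rate, level0) -
                   first_rising_crossing(times, light, level0))
  bw <- duration / n_bins
  shift <- stats::uniroot(function(s) measured_diff(s) - delta,
                          interval = s0 + c(-1.5, 1.5) * bw,
                          extendInt = "yes", tol = 1e-6)$root
  dark <- resp_at(shift) / spec$amplitude_ratio + spec$baseline_rate
  list(times = times, light = light, dark = dark, duration = duration,
       shift = shift, sigma = sigma)
}

#' Draw inhomogeneous Poisson spike times by thinning
#' @noRd
poisson_thinning <- function(times, rate, duration, n_sweeps) {
  lam_max <- max(rate)
  if (lam_max <= 0) {
    return(data.frame(sweep_index = integer(0), spike_time = numeric(0)))
  }
  n_tot <- stats::rpois(1L, n_sweeps * lam_max * duration)
  if (n_tot == 0L) {
    return(data.frame(sweep_index = integer(0), spike_time = numeric(0)))
  }
  tt <- stats::runif(n_tot, 0, duration)
  lam <- stats::approx(times, rate, xout = tt, rule = 2)$y
  keep <- stats::runif(n_tot) < lam / lam_max
  data.frame(sweep_index = sample.int(n_sweeps, sum(keep), replace = TRUE),
             spike_time = sort(tt[keep]))
}

#' Generate a synthetic spike-event table
#'
#' For each site, speed, polarity, and motion direction, spikes are drawn
#' from an inhomogeneous Poisson process (thinning) whose rate is the site's
#' light or dark template ([site_rate_templates()]) multiplied by a von-Mises
#' direction gain plus baseline. The gain is
#' \eqn{g(\theta) = \exp(\kappa(\cos(\theta - \theta_{pref}) - 1))} with
#' \eqn{\kappa = -\log(1 - DSI)/2}, so the noiseless direction selectivity
#' index equals the site's drawn DSI exactly. Each site's response peak is
#' jittered around mid-sweep to emulate receptive-field scatter. All
#' randomness flows from `spec$seed`; the same spec yields a bit-identical
#' table.
#'
#' @param spec a [site_population_spec()].
#' @return data frame with columns `site_id`, `direction`, `polarity`,
#'   `speed`, `sweep_index`, `spike_time`, plus attribute `"ground_truth"`
#'   (per-site DSI, preferred direction, jitter, and the per-speed true
#'   latency differences).
#' @export
generate_spike_tables <- function(spec) {
  if (!inherits(spec, "site_population_spec")) {
    stop_onoff("`spec` must be a site_population_spec",
               "onoffmotion_invalid_parameter")
  }
  set.seed(spec$seed)
  directions <- seq(0, 360 - 360 / spec$n_directions,
                    by = 360 / spec$n_directions)
  pref <- sample(directions, spec$n_sites, replace = TRUE)
  dsi <- pmin(pmax(stats::rnorm(spec$n_sites, spec$dsi_mean, spec$dsi_sd),
                   0.05), 0.95)
  jitter <- stats::rnorm(spec$n_sites, 0, spec$peak_time_jitter)
  out <- vector("list", 0L)
  for (i in seq_len(spec$n_sites)) {
    kappa <- -log(1 - dsi[i]) / 2
    gain <- exp(kappa * (cos((directions - pref[i]) * pi / 180) - 1))
    for (sp in spec$speeds) {
      delta <- spec$true_latency_difference[[as.character(sp)]]
      duration <- spec$screen_traverse / sp
      # keep the jittered peak comfortably inside the sweep
      center <- duration / 2 +
        max(min(jitter[i], 0.3 * duration), -0.3 * duration)
      tmpl <- site_rate_templates(spec, sp, delta, center = center)
      for (pol in c("light", "dark")) {
        resp <- if (pol == "light") tmpl$light else tmpl$dark
        shape <- resp - spec$baseline_rate
        for (d in seq_along(directions)) {
          rate <- gain[d] * shape + spec$baseline_rate
          sp_df <- poisson_thinning(tmpl$times, rate, duration, spec$n_sweeps)
          if (nrow(sp_df) == 0L) next
          sp_df$site_id <- i
          sp_df$direction <- directions[d]
          sp_df$polarity <- pol
          sp_df$speed <- sp
          out[[length(out) + 1L]] <- sp_df
        }
      }
    }
  }
  cols <- c("site_id", "direction", "polarity", "speed", "sweep_index",
            "spike_time")
  tab <- if (length(out) == 0L) {
    as.data.frame(stats::setNames(
      list(integer(0), numeric(0), character(0), numeric(0), integer(0),
           numeric(0)), cols))
  } else {
    do.call(rbind, out)[, cols]
  }
  rownames(tab) <- NULL
  attr(tab, "ground_truth") <- list(
    dsi = dsi, preferred_direction = pref, jitter = jitter,
    true_latency_difference = spec$true_latency_difference,
    amplitude_ratio = spec$amplitude_ratio
  )
  tab
}

#' Specification of a synthetic 2AFC observer pool
#'
#' Observer model for motion-direction trials: accuracy follows a cumulative
#' Gaussian in log contrast,
#' \eqn{P(correct \mid c) = 0.5 + (0.5 - \lambda)\,\Phi(\beta \log(|c|/c_{50}))},
#' and reaction time follows a hyperbolic law in normalized contrast,
#' \eqn{RT = (t_0 + k\,c_{50}/|c|)\,e^{\epsilon}} with Gaussian
#' \eqn{\epsilon}, censored at the 1 s response deadline (the trial is then
#' prompted: it still counts toward accuracy but carries no RT). Both laws
#' are generator choices, not claims about the underlying experiments; they
#' are configurable here.
#'
#' @param n_subjects number of subjects (default 6).
#' @param speeds stimulus speeds, deg/s (default 1, 3, 10, 30).
#' @param c50_light,c50_dark half-performance contrasts per speed (named by
#'   speed, or scalar). Defaults make light more sensitive at low speed with
#'   the gap closing as speed rises.
#' @param beta psychometric slope in log-contrast units.
#' @param lapse lapse rate in \[0, 0.1\].
#' @param t0 reaction-time floor, s.
#' @param k reaction-time gain, s per normalized-contrast unit.
#' @param rt_sdlog sd of the multiplicative lognormal RT noise.
#' @param contrast_sd sd of the zero-mean Gaussian from which signed
#'   contrasts are sampled.
#' @param deadline response deadline after the midpoint time, s (protocol: 1).
#' @param seed integer seed.
#' @return an object of class `"observer_spec"`.
#' @export
observer_spec <- function(n_subjects = 6,
                          speeds = c(1, 3, 10, 30),
                          c50_light = c(`1` = 0.020, `3` = 0.025,
                                        `10` = 0.035, `30` = 0.060),
                          c50_dark = c(`1` = 0.032, `3` = 0.038,
                                       `10` = 0.045, `30` = 0.065),
                          beta = 2,
                          lapse = 0.02,
                          t0 = 0.25,
                          k = 0.06,
                          rt_sdlog = 0.15,
                          contrast_sd = 0.08,
                          deadline = 1,
                          seed = 1) {
  expand <- function(x) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, length(speeds)), as.character(speeds))
    }
    missing <- setdiff(as.character(speeds), names(x))
    if (length(missing) > 0L) {
      stop_onoff(sprintf("no c50 for speed(s) %s",
                         paste(missing, collapse = ", ")),
                 "onoffmotion_config_error")
    }
    if (any(x <= 0)) {
      stop_onoff("c50 values must be positive", "onoffmotion_invalid_parameter")
    }
    x
  }
  if (lapse < 0 || lapse > 0.1) {
    stop_onoff("`lapse` must lie in [0, 0.1]", "onoffmotion_invalid_parameter")
  }
  structure(
    list(n_subjects = n_subjects, speeds = speeds,
         c50_light = expand(c50_light), c50_dark = expand(c50_dark),
         beta = beta, lapse = lapse, t0 = t0, k = k, rt_sdlog = rt_sdlog,
         contrast_sd = contrast_sd, deadline = deadline, seed = seed),
    class = "observer_spec"
  )
}

#' Generate a synthetic 2AFC trial table
#'
#' Per trial: a signed contrast is drawn from a zero-mean Gaussian (negative
#' values are dark stimuli), the true direction is left or right with equal
#' probability, correctness follows the observer's psychometric law, and the
#' reaction time follows its RT law, censored at the deadline (censored
#' trials are prompted and carry `rt = NA`). Deterministic given `spec$seed`.
#'
#' @param spec an [observer_spec()].
#' @param n_trials_per_subject trials per subject and speed (> 0).
#' @param speeds speeds to generate (default: `spec$speeds`).
#' @return data frame with columns `subject_id`, `speed`, `contrast`,
#'   `true_direction`, `choice`, `correct`, `rt`, `prompted`.
#' @export
generate_trial_table <- function(spec, n_trials_per_subject = 400,
                                 speeds = NULL) {
  if (!inherits(spec, "observer_spec")) {
    stop_onoff("`spec` must be an observer_spec", "onoffmotion_invalid_parameter")
  }
  if (n_trials_per_subject <= 0) {
    stop_onoff("`n_trials_per_subject` must be positive",
               "onoffmotion_invalid_parameter")
  }
  if (is.null(speeds)) speeds <- spec$speeds
  set.seed(spec$seed)
  grid <- expand.grid(subject_id = seq_len(spec$n_subjects),
                      speed = speeds,
                      trial = seq_len(n_trials_per_subject))
  n <- nrow(grid)
  contrast <- stats::rnorm(n, 0, spec$contrast_sd)
  polarity <- ifelse(contrast > 0, "light", "dark")
  cmag <- abs(contrast)
  c50 <- ifelse(polarity == "light",
                spec$c50_light[as.character(grid$speed)],
                spec$c50_dark[as.character(grid$speed)])
  z <- spec$beta * log(cmag / c50)
  p_correct <- 0.5 + (0.5 - spec$lapse) * stats::pnorm(z)
  p_correct[cmag == 0] <- 0.5
  true_direction <- ifelse(stats::runif(n) < 0.5, "left", "right")
  correct <- stats::runif(n) < p_correct
  choice <- ifelse(correct, true_direction,
                   ifelse(true_direction == "left", "right", "left"))
  rt_raw <- (spec$t0 + spec$k * c50 / cmag) *
    exp(stats::rnorm(n, 0, spec$rt_sdlog))
  prompted <- !is.finite(rt_raw) | rt_raw > spec$deadline
  rt <- ifelse(prompted, NA_real_, rt_raw)
  out <- data.frame(
    subject_id = grid$subject_id, speed = grid$speed, contrast = contrast,
    true_direction = true_direction, choice = choice, correct = correct,
    rt = rt, prompted = prompted
  )
  attr(out, "ground_truth") <- spec
  out
}
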