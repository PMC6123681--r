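# Model-based peak alignment: each recording site's receptive field sits at a
# slightly different screen position, so responses peak at different times.
# A Gaussian-plus-line fit locates each site's peak, and time courses are
# shifted so the fitted peak sits at time zero before averaging over sites.

#' Fit a Gaussian profile plus a linear trend
#'
#' Least-squares fit of \eqn{a \exp(-(t-\mu)^2 / (2 w^2)) + b t + c} to a
#' response time course, used to locate the response peak for alignment.
#' Fitting uses Levenberg-Marquardt with box bounds
#' (`minpack.lm::nlsLM`): `w` is kept between half a bin and the full span,
#' and `mu` inside the sampled window. Initial values are `a = max - min`,
#' `mu` at the maximum sample, `w = span / 10`, with the linear part seeded
#' from a straight-line fit to the first and last quartiles of samples.
#'
#' @param rates numeric vector of (smoothed) rates, length >= 7, non-constant.
#' @param times sample times (s); default: unit-spaced bin centers.
#' @return an object of class `"gauss_linear_fit"`: `amplitude`, `peak_time`,
#'   `width`, `slope`, `intercept`, `rss`, `fitted`.
#' @export
#' @examples
#' t <- seq(0, 8, length.out = 35)
#' y <- 40 * exp(-(t - 3)^2 / (2 * 0.6^2)) + 0.5 * t + 2
#' fit_gauss_linear(y, t)$peak_time
fit_gauss_linear <- function(rates, times = NULL) {
  n <- length(rates)
  if (n < 7L) {
    stop_onoff("need at least 7 samples to fit", "onoffmotion_fit_error")
  }
  if (is.null(times)) times <- seq_len(n) - 0.5
  if (length(times) != n) {
    stop_onoff("`times` and `rates` lengths differ", "onoffmotion_invalid_input")
  }
  if (max(rates) - min(rates) <= 0) {
    stop_onoff("constant input; Gaussian peak undefined", "onoffmotion_fit_error")
  }
  span <- max(times) - min(times)
  bin_width <- span / (n - 1)
  q <- max(2L, floor(n / 4))
  edge_idx <- c(seq_len(q), seq(n - q + 1L, n))
  line0 <- stats::lm.fit(cbind(1, times[edge_idx]), rates[edge_idx])$coefficients
  start <- list(a = max(rates) - min(rates),
                mu = times[which.max(rates)],
                w = span / 10,
                b = unname(line0[2L]),
                c = unname(line0[1L]))
  lower <- c(a = 0, mu = min(times), w = bin_width / 2,
             b = -Inf, c = -Inf)
  upper <- c(a = Inf, mu = max(times), w = span, b = Inf, c = Inf)
  df <- data.frame(t = times, y = rates)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(t - mu)^2 / (2 * w^2)) + b * t + c,
      data = df, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop_onoff(sprintf("Gaussian-plus-line fit failed: %s",
                         conditionMessage(e)),
                 "onoffmotion_fit_error")
    }
  )
  cf <- stats::coef(fit)
  structure(
    list(amplitude = unname(cf["a"]), peak_time = unname(cf["mu"]),
         width = unname(cf["w"]), slope = unname(cf["b"]),
         intercept = unname(cf["c"]),
         rss = sum(stats::residuals(fit)^2),
         fitted = as.numeric(stats::fitted(fit))),
    class = "gauss_linear_fit"
  )
}

#' @export
print.gauss_linear_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian + line fit: amplitude %.3g, peak at %.4g s, width %.3g s (rss %.3g)\n",
    x$amplitude, x$peak_time, x$width, x$rss))
  invisible(x)
}

#' Shift site time courses to their fitted peaks and average
#'
#' Each site's trace is translated so its fitted peak time sits at zero
#' (sub-bin shifts by linear interpolation), then all traces are averaged
#' pointwise on a common grid at the native bin width covering the
#' intersection of the shifted supports.
#'
#' @param traces list of numeric rate vectors, one per site, on a common time
#'   grid; at least 2.
#' @param peak_times numeric vector of fitted peak times (s), one per site.
#' @param times the common time grid of the input traces (s).
#' @return a `"response_timecourse"`: `times` (shifted grid, peak near 0),
#'   `rates` (mean over sites), `n_sites`, and `site_rates` (matrix of the
#'   shifted per-site traces used).
#' @export
align_and_average <- function(traces, peak_times, times) {
  if (length(traces) < 2L) {
    stop_onoff("need at least 2 sites to average", "onoffmotion_insufficient_data")
  }
  if (length(peak_times) != length(traces)) {
    stop_onoff("`peak_times` must have one entry per trace",
               "onoffmotion_invalid_input")
  }
  step <- times[2L] - times[1L]
  lo <- max(min(times) - peak_times)
  hi <- min(max(times) - peak_times)
  if (hi <= lo) {
    stop_onoff("shifted supports do not overlap", "onoffmotion_insufficient_data")
  }
  grid <- seq(lo, hi, by = step)
  shifted <- vapply(seq_along(traces), function(i) {
    stats::approx(times - peak_times[i], traces[[i]], xout = grid,
                  rule = 2)$y
  }, numeric(length(grid)))
  structure(
    list(times = grid, rates = rowMeans(shifted),
         n_sites = length(traces), site_rates = t(shifted)),
    class = "response_timecourse"
  )
}
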