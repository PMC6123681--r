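# Half-amplitude latency differences between mean light and dark time
# courses, site-level bootstrap confidence intervals, and the top-level
# spike-table analysis.

#' Construct a latency result
#' @noRd
latency_result <- function(latency_light, latency_dark,
                           ci_low = NA_real_, ci_high = NA_real_,
                           n_boot_failed = NA_integer_) {
  structure(
    list(latency_light = latency_light, latency_dark = latency_dark,
         difference = latency_dark - latency_light,
         ci_low = ci_low, ci_high = ci_high,
         n_boot_failed = n_boot_failed),
    class = "latency_result"
  )
}

#' @export
print.latency_result <- function(x, ...) {
  cat(sprintf("light %.2f ms, dark %.2f ms, dark - light = %.2f ms",
              1000 * x$latency_light, 1000 * x$latency_dark,
              1000 * x$difference))
  if (is.finite(x$ci_low)) {
    cat(sprintf(" [95%% CI %.2f, %.2f]", 1000 * x$ci_low, 1000 * x$ci_high))
  }
  cat("\n")
  invisible(x)
}

#' Dark-minus-light latency difference on mean time courses
#'
#' The reference level is half the peak of the lower-amplitude mean (under
#' cortical OFF dominance, the light response). Latency per polarity is the
#' first rising-edge crossing of that level, linearly interpolated; the
#' difference is dark minus light, so positive values mean lights lead.
#'
#' @param mean_light,mean_dark `"response_timecourse"` objects (or lists with
#'   `times`/`rates`) on a common time grid.
#' @return a `"latency_result"` (CI fields empty).
#' @export
latency_difference <- function(mean_light, mean_dark) {
  if (length(mean_light$times) != length(mean_dark$times) ||
      any(abs(mean_light$times - mean_dark$times) > 1e-9)) {
    stop_onoff("light and dark traces must share a common time grid",
               "onoffmotion_invalid_input")
  }
  ref <- min(max(mean_light$rates, na.rm = TRUE),
             max(mean_dark$rates, na.rm = TRUE))
  lat_l <- latency_at_half_reference(mean_light, ref)
  lat_d <- latency_at_half_reference(mean_dark, ref)
  latency_result(lat_l, lat_d)
}

#' Bootstrap confidence interval for the latency difference
#'
#' Recording sites are the resampling unit: each of `n_boot` replicates draws
#' sites with replacement from the aligned per-site traces, averages them per
#' polarity, and recomputes the latency difference. The CI is the percentile
#' interval of the replicate differences; the point estimate comes from the
#' full sample. Replicates in which a trace never reaches the reference level
#' are dropped and counted; more than 20% such failures aborts with an
#' unstable-estimate error.
#'
#' @param light_traces,dark_traces matrices of aligned per-site rates (one row
#'   per site) on the grid `times`; the same sites in the same row order.
#' @param times common time grid (s).
#' @param n_boot number of bootstrap subsamples (default 200).
#' @param conf_level confidence level (default 0.95).
#' @return a `"latency_result"` with `ci_low`/`ci_high` filled in.
#' @export
bootstrap_latency_ci <- function(light_traces, dark_traces, times,
                                 n_boot = 200, conf_level = 0.95) {
  light_traces <- as.matrix(light_traces)
  dark_traces <- as.matrix(dark_traces)
  n_sites <- nrow(light_traces)
  if (n_sites < 2L || nrow(dark_traces) != n_sites) {
    stop_onoff("need the same >= 2 sites for both polarities",
               "onoffmotion_insufficient_data")
  }
  diff_of <- function(rows) {
    ml <- list(times = times, rates = colMeans(light_traces[rows, , drop = FALSE]))
    md <- list(times = times, rates = colMeans(dark_traces[rows, , drop = FALSE]))
    latency_difference(ml, md)
  }
  point <- diff_of(seq_len(n_sites))
  reps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(n_sites, n_sites, replace = TRUE)
    reps[b] <- tryCatch(diff_of(rows)$difference,
                        onoffmotion_no_crossing = function(e) NA_real_)
  }
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.2 * n_boot) {
    stop_onoff(sprintf(
      "%d of %d bootstrap replicates had no level crossing; estimate unstable",
      n_failed, n_boot), "onoffmotion_unstable_estimate")
  }
  alpha <- (1 - conf_level) / 2
  qs <- stats::quantile(reps[!is.na(reps)], c(alpha, 1 - alpha), names = FALSE)
  latency_result(point$latency_light, point$latency_dark,
                 ci_low = qs[1L], ci_high = qs[2L],
                 n_boot_failed = n_failed)
}

#' Analyze a spike-event table for light/dark latency differences
#'
#' Full electrophysiology chain: per site, spikes are binned into 35-bin
#' PSTHs per direction, polarity, and speed; sweeps at 15 and 17.3 deg/s are
#' pooled and labeled 16.15 deg/s; the direction selectivity index is
#' computed from the light+dark combined, smoothed tuning (pooled over
#' speeds) and sites with DSI <= `dsi_threshold` are excluded. For each
#' retained site and speed, a Gaussian-plus-line fit to the combined
#' preferred-direction time course locates the site's response peak, and the
#' same shift is applied to the light and the dark trace (a per-polarity
#' shift would subtract out the latency difference being measured). Shifted
#' traces are averaged over sites per polarity, the dark-minus-light latency
#' difference is read at half the lower mean peak, and a site-level bootstrap
#' gives its confidence interval.
#'
#' @param spikes data frame with columns `site_id`, `direction` (deg),
#'   `polarity` (`"light"`/`"dark"`), `speed` (deg/s), `sweep_index`,
#'   `spike_time` (s from sweep onset).
#' @param screen_traverse distance the bar travels, deg; sweep duration is
#'   `screen_traverse / speed`.
#' @param n_bins PSTH bins per sweep (default 35).
#' @param sigma_bins smoothing sd in bins (default 1).
#' @param dsi_threshold direction-selectivity cutoff (strict, default 0.25).
#' @param n_sweeps stimulus repeats per condition (default 4).
#' @param n_boot bootstrap subsamples (default 200).
#' @param conf_level bootstrap confidence level (default 0.95).
#' @param merge_speeds pool 15 and 17.3 deg/s into 16.15 (default TRUE).
#' @param seed seed for the bootstrap; `NULL` leaves the RNG state alone.
#' @return an object of class `"psth_latency"`: a per-speed data frame
#'   (`speed`, `n_sites`, `latency_light`, `latency_dark`, `difference`,
#'   `ci_low`, `ci_high`, seconds) plus diagnostics in attributes
#'   (`n_sites_total`, `n_excluded_dsi`, `fit_failures`, `site_dsi`).
#' @export
analyze_psth <- function(spikes,
                         screen_traverse = 40,
                         n_bins = 35,
                         sigma_bins = 1,
                         dsi_threshold = 0.25,
                         n_sweeps = 4,
                         n_boot = 200,
                         conf_level = 0.95,
                         merge_speeds = TRUE,
                         seed = NULL) {
  assert_columns(spikes, c("site_id", "direction", "polarity", "speed",
                           "sweep_index", "spike_time"), "spikes")
  if (!is.null(seed)) set.seed(seed)
  site_ids <- sort(unique(spikes$site_id))
  directions <- sort(unique(spikes$direction))
  speeds <- sort(unique(spikes$speed))

  # --- per-site PSTHs (list site -> speed -> polarity -> matrix dir x bin) --
  rate_tabs <- lapply(site_ids, function(sid) {
    s_rows <- spikes[spikes$site_id == sid, , drop = FALSE]
    per_speed <- lapply(speeds, function(sp) {
      dur <- screen_traverse / sp
      sp_rows <- s_rows[s_rows$speed == sp, , drop = FALSE]
      lapply(c(light = "light", dark = "dark"), function(pol) {
        p_rows <- sp_rows[sp_rows$polarity == pol, , drop = FALSE]
        t(vapply(directions, function(d) {
          ps <- bin_psth(p_rows$spike_time[p_rows$direction == d],
                         sweep_duration = dur, n_bins = n_bins,
                         n_sweeps = n_sweeps)
          ps$counts
        }, numeric(n_bins)))
      })
    })
    names(per_speed) <- as.character(speeds)
    per_speed
  })
  names(rate_tabs) <- as.character(site_ids)

  # --- optionally pool the two near-identical intermediate speeds ----------
  pool_pair <- merge_speeds && all(c(15, 17.3) %in% speeds)
  if (pool_pair) {
    for (sid in as.character(site_ids)) {
      a <- rate_tabs[[sid]][["15"]]
      b <- rate_tabs[[sid]][["17.3"]]
      rate_tabs[[sid]][["16.15"]] <- list(light = a$light + b$light,
                                          dark = a$dark + b$dark)
      rate_tabs[[sid]][["15"]] <- NULL
      rate_tabs[[sid]][["17.3"]] <- NULL
    }
    speeds <- sort(c(setdiff(speeds, c(15, 17.3)), 16.15))
  }
  sweeps_for <- function(sp) if (pool_pair && sp == 16.15) 2 * n_sweeps else n_sweeps
  duration_for <- function(sp) {
    if (pool_pair && sp == 16.15) {
      mean(screen_traverse / c(15, 17.3))
    } else {
      screen_traverse / sp
    }
  }

  # --- direction selectivity, pooled over speeds ---------------------------
  site_summaries <- lapply(as.character(site_ids), function(sid) {
    # counts are summed over speeds on the normalized 35-bin grid, then
    # converted to a rate with the mean bin width, combined across polarity,
    # smoothed, and the per-direction maximum taken
    light <- Reduce(`+`, lapply(rate_tabs[[sid]], `[[`, "light"))
    dark <- Reduce(`+`, lapply(rate_tabs[[sid]], `[[`, "dark"))
    ds <- tryCatch(
      direction_selectivity(light, dark, directions, sigma_bins = sigma_bins),
      onoffmotion_undefined_dsi = function(e) NULL
    )
    if (is.null(ds)) return(NULL)
    list(site_id = sid, dsi = ds$dsi,
         preferred_direction = ds$preferred_direction)
  })
  site_summaries <- Filter(Negate(is.null), site_summaries)
  retained <- filter_sites(site_summaries, threshold = dsi_threshold)
  n_excluded <- length(site_ids) - length(retained)
  if (length(retained) < 2L) {
    stop_onoff("fewer than 2 direction-selective sites retained",
               "onoffmotion_insufficient_data")
  }

  # --- per-speed alignment, averaging, latency, bootstrap ------------------
  fit_failures <- 0L
  rows <- vector("list", length(speeds))
  for (k in seq_along(speeds)) {
    sp <- speeds[k]
    dur <- duration_for(sp)
    bw <- dur / n_bins
    times <- (seq_len(n_bins) - 0.5) * bw
    lt <- list(); dk <- list(); pk <- numeric(0)
    for (s in retained) {
      tab <- rate_tabs[[s$site_id]][[as.character(sp)]]
      i_dir <- match(s$preferred_direction, directions)
      denom <- sweeps_for(sp) * bw
      l_rate <- smooth_rates(tab$light[i_dir, ] / denom, sigma_bins)
      d_rate <- smooth_rates(tab$dark[i_dir, ] / denom, sigma_bins)
      fit <- tryCatch(fit_gauss_linear(l_rate + d_rate, times),
                      onoffmotion_fit_error = function(e) NULL)
      if (is.null(fit)) {
        fit_failures <- fit_failures + 1L
        next
      }
      lt[[length(lt) + 1L]] <- l_rate
      dk[[length(dk) + 1L]] <- d_rate
      pk <- c(pk, fit$peak_time)
    }
    if (length(lt) < 2L) {
      stop_onoff(sprintf("fewer than 2 usable sites at %g deg/s", sp),
                 "onoffmotion_insufficient_data")
    }
    avg_l <- align_and_average(lt, pk, times)
    avg_d <- align_and_average(dk, pk, times)
    res <- bootstrap_latency_ci(avg_l$site_rates, avg_d$site_rates,
                                avg_l$times, n_boot = n_boot,
                                conf_level = conf_level)
    rows[[k]] <- data.frame(
      speed = sp, n_sites = length(lt),
      latency_light = res$latency_light, latency_dark = res$latency_dark,
      difference = res$difference, ci_low = res$ci_low, ci_high = res$ci_high
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("psth_latency", "data.frame")
  attr(out, "n_sites_total") <- length(site_ids)
  attr(out, "n_excluded_dsi") <- n_excluded
  attr(out, "fit_failures") <- fit_failures
  attr(out, "site_dsi") <- vapply(site_summaries, `[[`, numeric(1), "dsi")
  out
}

#' @export
print.psth_latency <- function(x, ...) {
  cat("Cortical light/dark latency differences (half-amplitude criterion)\n")
  cat(sprintf("Sites: %d analyzed, %d excluded by the DSI > 0.25 filter\n\n",
              attr(x, "n_sites_total") - attr(x, "n_excluded_dsi"),
              attr(x, "n_excluded_dsi")))
  df <- data.frame(
    speed_deg_s = x$speed, n_sites = x$n_sites,
    latency_light_ms = round(1000 * x$latency_light, 2),
    latency_dark_ms = round(1000 * x$latency_dark, 2),
    difference_ms = round(1000 * x$difference, 2),
    ci_low_ms = round(1000 * x$ci_low, 2),
    ci_high_ms = round(1000 * x$ci_high, 2)
  )
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.psth_latency <- function(object, ...) {
  print(object)
  ff <- attr(object, "fit_failures")
  if (!is.null(ff) && ff > 0) {
    cat(sprintf("\nAlignment fit failures: %d site-speed pairs excluded\n", ff))
  }
  invisible(object)
}

#' @export
plot.psth_latency <- function(x, ...) {
  ylim <- range(1000 * c(x$ci_low, x$ci_high, x$difference), na.rm = TRUE)
  graphics::plot(x$speed, 1000 * x$difference, log = "x", pch = 19,
                 ylim = ylim, xlab = "speed (deg/s)",
                 ylab = "dark - light latency (ms)", ...)
  graphics::arrows(x$speed, 1000 * x$ci_low, x$speed, 1000 * x$ci_high,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
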