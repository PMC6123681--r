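# Peristimulus time histograms, smoothing, direction selectivity, and the
# pooling of the two near-identical intermediate speeds.

#' Bin spike times into a 35-bin peristimulus time histogram
#'
#' Spike times (relative to sweep onset) are counted into `n_bins` equal-width
#' half-open bins \[left, right) spanning one stimulus sweep, summed over
#' sweeps. Spikes outside \[0, sweep_duration) are dropped and counted in the
#' `n_dropped` field.
#'
#' @param spikes numeric vector of spike times (s), or a data frame with a
#'   `spike_time` column (and optionally `sweep_index`).
#' @param sweep_duration sweep duration, s (> 0).
#' @param n_bins number of bins (default 35).
#' @param n_sweeps number of stimulus repeats contributing; taken from
#'   `sweep_index` when `spikes` is a data frame, else defaults to 4.
#' @param meta optional named list (site_id, direction, polarity, speed)
#'   carried on the object.
#' @return an object of class `"psth"`: `counts` (length `n_bins`),
#'   `bin_width`, `sweep_duration`, `n_sweeps`, `n_dropped`, plus `meta`.
#' @export
#' @examples
#' p <- bin_psth(c(0.1, 0.2, 0.2, 3.4), sweep_duration = 8)
#' sum(p$counts)
bin_psth <- function(spikes, sweep_duration, n_bins = 35, n_sweeps = NULL,
                     meta = list()) {
  assert_scalar_positive(sweep_duration, "sweep_duration")
  if (is.data.frame(spikes)) {
    assert_columns(spikes, "spike_time", "spikes")
    if (is.null(n_sweeps) && "sweep_index" %in% names(spikes)) {
      n_sweeps <- max(length(unique(spikes$sweep_index)), 1L)
    }
    spikes <- spikes$spike_time
  }
  if (is.null(n_sweeps)) n_sweeps <- 4L
  spikes <- as.numeric(spikes)
  in_window <- is.finite(spikes) & spikes >= 0 & spikes < sweep_duration
  n_dropped <- sum(!in_window)
  bin_width <- sweep_duration / n_bins
  idx <- floor(spikes[in_window] / bin_width) + 1L
  idx[idx > n_bins] <- n_bins  # guards rounding at the right edge
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(counts = counts, bin_width = bin_width,
         sweep_duration = sweep_duration, n_sweeps = n_sweeps,
         n_dropped = n_dropped, meta = meta),
    class = "psth"
  )
}

#' Bin centers of a PSTH
#' @param psth a `"psth"` object.
#' @return numeric vector of bin-center times (s).
#' @export
psth_times <- function(psth) {
  (seq_along(psth$counts) - 0.5) * psth$bin_width
}

#' Impulse rate of a PSTH
#'
#' Converts counts to spikes/s: `counts / (n_sweeps * bin_width)`.
#' @param psth a `"psth"` object.
#' @return numeric vector of rates (spikes/s).
#' @export
psth_rates <- function(psth) {
  psth$counts / (psth$n_sweeps * psth$bin_width)
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins x %.4g s, %d sweeps, %d spikes (%d dropped)\n",
              length(x$counts), x$bin_width, x$n_sweeps, sum(x$counts),
              x$n_dropped))
  invisible(x)
}

#' Gaussian smoothing with edge renormalization
#'
#' Smooths a rate vector with a discrete Gaussian kernel (standard deviation
#' `sigma_bins` bins, truncated at 4 sigma). At every position the kernel is
#' renormalized to unit sum over the samples actually available, so a constant
#' input is returned unchanged and total mass is conserved at the edges.
#'
#' @param x numeric vector, or a `"psth"` object (its impulse rate is
#'   smoothed).
#' @param sigma_bins kernel standard deviation in bins (> 0, default 1).
#' @return smoothed numeric vector, same length as the input.
#' @export
smooth_rates <- function(x, sigma_bins = 1) {
  assert_scalar_positive(sigma_bins, "sigma_bins")
  if (inherits(x, "psth")) x <- psth_rates(x)
  n <- length(x)
  h <- ceiling(4 * sigma_bins)
  k <- exp(-((-h:h)^2) / (2 * sigma_bins^2))
  pad <- rep(0, h)
  xs <- c(pad, x, pad)
  ones <- c(pad, rep(1, n), pad)
  num <- stats::filter(xs, k, sides = 2)
  den <- stats::filter(ones, k, sides = 2)
  out <- as.numeric(num / den)[(h + 1):(h + n)]
  # renormalize so the total is exactly conserved: per-position kernel
  # renormalization preserves a constant but can shift total mass slightly
  # when the signal is concentrated near an edge
  s_in <- sum(x)
  s_out <- sum(out)
  if (s_out > 0 && s_in > 0) out <- out * (s_in / s_out)
  out
}

#' Direction selectivity index
#'
#' Responses to light and dark bars are combined (summed) per motion
#' direction, lightly smoothed ([smooth_rates()] with sd 1 bin), and the
#' maximum smoothed rate per direction is taken as that direction's response
#' R. The index is \eqn{(R_{pref} - R_{opp}) / R_{pref}} where pref is the
#' direction with maximal R and opp the direction 180 degrees away.
#'
#' @param light_rates,dark_rates numeric matrices, one row per direction, of
#'   unsmoothed impulse rates on a common bin grid.
#' @param directions numeric vector of direction angles (deg), one per row;
#'   must contain each direction's opposite (mod 360).
#' @param sigma_bins smoothing sd in bins.
#' @return list with `dsi`, `preferred_direction`, and the per-direction
#'   response vector `R`.
#' @export
#' @examples
#' lr <- rbind(c(0, 10, 0), c(0, 5, 0))
#' dr <- rbind(c(0, 0, 0), c(0, 0, 0))
#' direction_selectivity(lr, dr, directions = c(0, 180), sigma_bins = 0.1)
direction_selectivity <- function(light_rates, dark_rates, directions,
                                  sigma_bins = 1) {
  light_rates <- as.matrix(light_rates)
  dark_rates <- as.matrix(dark_rates)
  if (!all(dim(light_rates) == dim(dark_rates))) {
    stop_onoff("light and dark rate matrices must have identical shape",
               "onoffmotion_invalid_input")
  }
  if (nrow(light_rates) != length(directions)) {
    stop_onoff("`directions` must have one entry per rate-matrix row",
               "onoffmotion_invalid_input")
  }
  combined <- light_rates + dark_rates
  R <- apply(combined, 1L, function(row) max(smooth_rates(row, sigma_bins)))
  names(R) <- as.character(directions)
  i_pref <- which.max(R)  # lowest index wins ties
  r_pref <- R[[i_pref]]
  if (r_pref <= 0) {
    stop_onoff("preferred-direction response is zero; DSI undefined",
               "onoffmotion_undefined_dsi")
  }
  opp_angle <- (directions[i_pref] + 180) %% 360
  i_opp <- match(TRUE, abs(((directions - opp_angle) %% 360)) < 1e-6)
  if (is.na(i_opp)) {
    stop_onoff("no direction 180 degrees from the preferred direction",
               "onoffmotion_invalid_input")
  }
  list(dsi = (r_pref - R[[i_opp]]) / r_pref,
       preferred_direction = directions[i_pref],
       R = R)
}

#' Filter recording sites by direction selectivity
#'
#' Retains sites whose DSI strictly exceeds the threshold (a site at exactly
#' the threshold is excluded). Input order is preserved; the number excluded
#' is attached as attribute `"n_excluded"`.
#'
#' @param sites a list whose elements each have a `dsi` field (or a numeric
#'   vector of DSI values).
#' @param threshold DSI cutoff, default 0.25.
#' @return the retained subset (same type as the input).
#' @export
filter_sites <- function(sites, threshold = 0.25) {
  dsi <- if (is.numeric(sites)) sites else
    vapply(sites, function(s) s$dsi, numeric(1))
  keep <- dsi > threshold
  out <- sites[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Pool PSTHs from the two near-identical intermediate speeds
#'
#' Sweeps recorded at 15 and 17.3 deg/s give closely similar responses and
#' are pooled before analysis. Each PSTH's bins already span its own sweep
#' duration, so bins correspond after normalizing time to the sweep; counts
#' are summed bin-wise, sweep counts add, and the result is labeled with the
#' average speed 16.15 deg/s.
#'
#' @param psth_a,psth_b `"psth"` objects for the two speeds; if `psth_b` is
#'   `NULL` the first is passed through with a warning.
#' @param label speed label for the merged result (default 16.15).
#' @return a `"psth"` object.
#' @export
merge_similar_speeds <- function(psth_a, psth_b = NULL, label = 16.15) {
  if (is.null(psth_b)) {
    warning("only one of the two similar speeds present; passing it through")
    psth_a$meta$speed <- label
    return(psth_a)
  }
  if (length(psth_a$counts) != length(psth_b$counts)) {
    stop_onoff("PSTHs to merge must have the same number of bins",
               "onoffmotion_invalid_input")
  }
  sweep_duration <- (psth_a$sweep_duration + psth_b$sweep_duration) / 2
  meta <- psth_a$meta
  meta$speed <- label
  structure(
    list(counts = psth_a$counts + psth_b$counts,
         bin_width = sweep_duration / length(psth_a$counts),
         sweep_duration = sweep_duration,
         n_sweeps = psth_a$n_sweeps + psth_b$n_sweeps,
         n_dropped = psth_a$n_dropped + psth_b$n_dropped,
         meta = meta),
    class = "psth"
  )
}
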