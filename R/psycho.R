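# Psychometric accuracy and reaction-time functions versus contrast,
# contrast-sensitivity extraction, and light/dark statistical comparisons.

#' Construct a psychometric curve
#'
#' Container for a binned psychometric function: proportion correct or mean
#' reaction time versus contrast magnitude, for one polarity (and optionally
#' one speed).
#'
#' @param bin_centers contrast magnitudes at bin centers (increasing).
#' @param values proportion correct in \[0, 1\] or mean RT in seconds.
#' @param n_per_bin trial counts per bin.
#' @param polarity `"light"` or `"dark"`.
#' @param measure `"accuracy"` or `"rt"`.
#' @param speed optional speed label (deg/s).
#' @return an object of class `"psychometric_curve"`.
#' @export
psychometric_curve <- function(bin_centers, values, n_per_bin,
                               polarity = c("light", "dark"),
                               measure = c("accuracy", "rt"),
                               speed = NULL) {
  polarity <- match.arg(polarity)
  measure <- match.arg(measure)
  if (length(bin_centers) != length(values) ||
      length(values) != length(n_per_bin)) {
    stop_onoff("curve fields must have equal length", "onoffmotion_invalid_input")
  }
  if (measure == "accuracy" && any(values < 0 | values > 1)) {
    stop_onoff("proportion correct must lie in [0, 1]",
               "onoffmotion_invalid_input")
  }
  o <- order(bin_centers)
  structure(
    list(bin_centers = bin_centers[o], values = values[o],
         n_per_bin = n_per_bin[o], polarity = polarity, measure = measure,
         speed = speed),
    class = "psychometric_curve"
  )
}

#' @export
print.psychometric_curve <- function(x, ...) {
  cat(sprintf("%s psychometric curve (%s%s): %d bins, %d trials\n",
              x$measure, x$polarity,
              if (is.null(x$speed)) "" else sprintf(", %g deg/s", x$speed),
              length(x$values), sum(x$n_per_bin)))
  invisible(x)
}

#' Select one polarity's trials
#' @noRd
polarity_rows <- function(trials, polarity) {
  if (polarity == "light") trials$contrast > 0 else trials$contrast < 0
}

#' Equal-count contrast-magnitude bins
#' @noRd
quantile_bins <- function(cmag, n_bins) {
  brks <- unique(stats::quantile(cmag, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brks) < 3L) brks <- range(cmag) + c(-1e-12, 1e-12)
  bin <- cut(cmag, breaks = brks, include.lowest = TRUE, labels = FALSE)
  bin
}

#' Accuracy psychometric function for one polarity
#'
#' Trials of the requested polarity (sign of the signed contrast) are binned
#' into equal-count bins of contrast magnitude; the value per bin is the
#' fraction of correct responses. Prompted trials count toward accuracy.
#'
#' @param trials data frame with columns `contrast` (signed fraction,
#'   negative = dark), `correct` (logical); optionally `speed`.
#' @param polarity `"light"` or `"dark"`.
#' @param n_bins number of equal-count bins (default 8).
#' @param speed optional speed filter (deg/s).
#' @return a [psychometric_curve()].
#' @export
build_accuracy_curve <- function(trials, polarity = c("light", "dark"),
                                 n_bins = 8, speed = NULL) {
  polarity <- match.arg(polarity)
  assert_columns(trials, c("contrast", "correct"), "trials")
  if (!is.null(speed)) trials <- trials[trials$speed == speed, , drop = FALSE]
  trials <- trials[polarity_rows(trials, polarity), , drop = FALSE]
  if (nrow(trials) == 0L) {
    stop_onoff(sprintf("no %s trials to bin", polarity),
               "onoffmotion_empty_curve")
  }
  cmag <- abs(trials$contrast)
  bin <- quantile_bins(cmag, n_bins)
  centers <- tapply(cmag, bin, mean)
  values <- tapply(trials$correct, bin, mean)
  n <- tapply(rep(1L, length(bin)), bin, sum)
  psychometric_curve(as.numeric(centers), as.numeric(values),
                     as.numeric(n), polarity, "accuracy", speed)
}

#' Reaction-time psychometric function for one polarity
#'
#' As [build_accuracy_curve()], but the value per bin is the mean (or median)
#' reaction time over unprompted responses; prompted trials and trials
#' without a timely response are excluded, and empty bins are omitted. This
#' is why RT curves start at higher contrasts than accuracy curves: faint
#' stimuli rarely yield a timely response.
#'
#' @inheritParams build_accuracy_curve
#' @param trials data frame with columns `contrast`, `rt` (s, `NA` when
#'   absent), `prompted` (logical).
#' @param aggregate `"mean"` (default) or `"median"` per bin.
#' @return a [psychometric_curve()].
#' @export
build_rt_curve <- function(trials, polarity = c("light", "dark"),
                           n_bins = 8, speed = NULL,
                           aggregate = c("mean", "median")) {
  polarity <- match.arg(polarity)
  aggregate <- match.arg(aggregate)
  assert_columns(trials, c("contrast", "rt", "prompted"), "trials")
  if (!is.null(speed)) trials <- trials[trials$speed == speed, , drop = FALSE]
  trials <- trials[polarity_rows(trials, polarity) & !trials$prompted &
                     !is.na(trials$rt), , drop = FALSE]
  if (nrow(trials) == 0L) {
    stop_onoff(sprintf("no unprompted %s responses to bin", polarity),
               "onoffmotion_empty_curve")
  }
  cmag <- abs(trials$contrast)
  bin <- quantile_bins(cmag, n_bins)
  agg <- if (aggregate == "mean") mean else stats::median
  centers <- tapply(cmag, bin, mean)
  values <- tapply(trials$rt, bin, agg)
  n <- tapply(rep(1L, length(bin)), bin, sum)
  psychometric_curve(as.numeric(centers), as.numeric(values),
                     as.numeric(n), polarity, "rt", speed)
}

#' Construct a sensitivity result
#' @noRd
sensitivity_result <- function(polarity, speed, criterion, threshold_contrast) {
  structure(
    list(polarity = polarity, speed = speed, criterion = criterion,
         threshold_contrast = threshold_contrast,
         sensitivity = 1 / threshold_contrast),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("%s (%s): threshold contrast %.4g, sensitivity %.4g\n",
              x$polarity, x$criterion, x$threshold_contrast, x$sensitivity))
  invisible(x)
}

#' Contrast sensitivity from an accuracy curve
#'
#' Finds the contrast at which proportion correct reaches `criterion_pc`
#' (default 0.75) by linear interpolation between the bracketing bins of the
#' pooled curve, and returns its reciprocal as sensitivity.
#'
#' @param curve an accuracy [psychometric_curve()], pooled over subjects.
#' @param criterion_pc criterion proportion correct (default 0.75).
#' @return a `"sensitivity_result"`.
#' @export
sensitivity_from_accuracy <- function(curve, criterion_pc = 0.75) {
  v <- curve$values
  if (all(v >= criterion_pc) || all(v < criterion_pc)) {
    stop_onoff("accuracy curve does not cross the criterion",
               "onoffmotion_no_threshold")
  }
  thr <- first_rising_crossing(curve$bin_centers, v, criterion_pc)
  sensitivity_result(curve$polarity, curve$speed, "PC_075", thr)
}

#' Contrast sensitivity from a reaction-time curve
#'
#' The criterion is the reaction time halfway between the pooled curve's
#' highest and lowest values; the threshold contrast is the first crossing of
#' that level coming from the high-RT (low-contrast) side, linearly
#' interpolated. Sensitivity is its reciprocal.
#'
#' @param curve an RT [psychometric_curve()], pooled over subjects.
#' @return a `"sensitivity_result"`.
#' @export
sensitivity_from_rt <- function(curve) {
  v <- curve$values
  if (max(v) - min(v) <= 0) {
    stop_onoff("flat reaction-time curve; halfway criterion undefined",
               "onoffmotion_no_threshold")
  }
  level <- (max(v) + min(v)) / 2
  # scan from low contrast (high RT): first drop through the level
  i <- which(v <= level)
  i <- i[i > 1L][1L]
  if (is.na(i)) {
    stop_onoff("reaction-time curve never falls through the halfway level",
               "onoffmotion_no_threshold")
  }
  thr <- curve$bin_centers[i - 1L] +
    (v[i - 1L] - level) / (v[i - 1L] - v[i]) *
    (curve$bin_centers[i] - curve$bin_centers[i - 1L])
  sensitivity_result(curve$polarity, curve$speed, "RT_halfway", thr)
}

#' F test for a contrast-polarity effect
#'
#' Ordinary-least-squares linear model with categorical subject and polarity
#' terms plus the stated polynomial covariates, following the factor
#' structures used for the light/dark comparisons: accuracy uses powers of
#' contrast magnitude 1-4; reaction time uses contrast magnitude and its
#' square; sensitivity uses speed, its square, and a polarity x speed
#' interaction. The polarity F statistic comes from a nested-model (Type II)
#' comparison: interactions involving polarity are excluded from both models
#' and the reduced model drops the polarity main effect.
#'
#' @param data data frame with columns `value`, `subject`, `polarity`, and
#'   `contrast` (magnitude) or `speed` as the design requires; optionally `n`
#'   (weights, e.g. trials per bin).
#' @param design `"accuracy"`, `"rt"`, or `"sensitivity"`.
#' @return list with `F`, `df1`, `df2`, `p`, and the full-model `fit`.
#' @export
polarity_anova <- function(data, design = c("accuracy", "rt", "sensitivity")) {
  design <- match.arg(design)
  need <- switch(design,
                 accuracy = c("value", "subject", "polarity", "contrast"),
                 rt = c("value", "subject", "polarity", "contrast"),
                 sensitivity = c("value", "subject", "polarity", "speed"))
  assert_columns(data, need, "data")
  data$subject <- factor(data$subject)
  data$polarity <- factor(data$polarity)
  w <- if ("n" %in% names(data)) data$n else NULL
  base_terms <- switch(design,
    accuracy = "contrast + I(contrast^2) + I(contrast^3) + I(contrast^4)",
    rt = "contrast + I(contrast^2)",
    sensitivity = "speed + I(speed^2)")
  reduced_f <- stats::as.formula(paste("value ~ subject +", base_terms))
  full_f <- stats::as.formula(paste("value ~ subject + polarity +", base_terms))
  reduced <- stats::lm(reduced_f, data = data, weights = w)
  full <- stats::lm(full_f, data = data, weights = w)
  X <- stats::model.matrix(full)
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[is.na(stats::coef(full))]
    stop_onoff(sprintf("design matrix is rank deficient (collinear: %s)",
                       paste(bad, collapse = ", ")),
               "onoffmotion_design_error")
  }
  cmp <- stats::anova(reduced, full)
  list(F = cmp$F[2L], df1 = cmp$Df[2L], df2 = cmp$Res.Df[2L],
       p = cmp$`Pr(>F)`[2L], fit = full)
}

#' Paired t test between light and dark per-subject values
#'
#' Two-sided paired t test on light-minus-dark differences. Degenerate
#' zero-variance differences (where `stats::t.test` refuses to run) are
#' reported explicitly: identical vectors give `t = 0, p = 1`; a constant
#' nonzero difference gives infinite `t` and `p = 0` with `degenerate = TRUE`.
#'
#' @param light,dark equal-length numeric vectors, one value per subject.
#' @return list with `t`, `df`, `p`, `mean_difference`, `degenerate`.
#' @export
paired_polarity_test <- function(light, dark) {
  if (length(light) != length(dark)) {
    stop_onoff("paired vectors must have equal length",
               "onoffmotion_invalid_input")
  }
  n <- length(light)
  if (n < 2L) {
    stop_onoff("need at least 2 subjects for a paired test",
               "onoffmotion_insufficient_data")
  }
  d <- light - dark
  if (stats::sd(d) == 0) {
    m <- mean(d)
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                df = n - 1L,
                p = if (m == 0) 1 else 0,
                mean_difference = m, degenerate = TRUE))
  }
  tt <- stats::t.test(light, dark, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = unname(tt$estimate),
       degenerate = FALSE)
}

#' Per-subject binned accuracy (or RT) table for the polarity ANOVA
#'
#' Builds the curve-level observations the polarity ANOVA runs on: one row
#' per subject x polarity x contrast bin, with the bin's proportion correct
#' (or mean RT), its trial count as weight, and the bin-center contrast.
#'
#' @param trials trial data frame (see [analyze_psycho()]).
#' @param measure `"accuracy"` or `"rt"`.
#' @param n_bins contrast bins per subject and polarity.
#' @param speed optional speed filter.
#' @return data frame with columns `subject`, `polarity`, `contrast`,
#'   `value`, `n`.
#' @export
binned_by_subject <- function(trials, measure = c("accuracy", "rt"),
                              n_bins = 8, speed = NULL) {
  measure <- match.arg(measure)
  assert_columns(trials, "subject_id", "trials")
  out <- list()
  for (subj in sort(unique(trials$subject_id))) {
    for (pol in c("light", "dark")) {
      tr <- trials[trials$subject_id == subj, , drop = FALSE]
      curve <- tryCatch(
        if (measure == "accuracy") {
          build_accuracy_curve(tr, pol, n_bins, speed)
        } else {
          build_rt_curve(tr, pol, n_bins, speed)
        },
        onoffmotion_empty_curve = function(e) NULL
      )
      if (is.null(curve)) next
      out[[length(out) + 1L]] <- data.frame(
        subject = subj, polarity = pol, contrast = curve$bin_centers,
        value = curve$values, n = curve$n_per_bin
      )
    }
  }
  do.call(rbind, out)
}

#' Analyze a 2AFC motion-trial table
#'
#' Full psychophysics chain per speed: pooled (across-subject) accuracy and
#' RT psychometric curves per polarity, contrast sensitivity from the
#' PC = 0.75 criterion and from the RT halfway criterion, the polarity ANOVA
#' on per-subject binned curves, and a paired t test on per-subject accuracy.
#'
#' @param trials data frame with columns `subject_id`, `speed`, `contrast`
#'   (signed fraction, negative = dark), `true_direction`, `choice`,
#'   `correct`, `rt` (s, `NA` if absent), `prompted` (logical).
#' @param speeds speeds to analyze; default: all present.
#' @param n_bins contrast bins for the pooled curves (default 8).
#' @return an object of class `"psycho_analysis"`: `$sensitivity` (data frame
#'   speed x polarity x criterion), `$anova` (per speed and measure),
#'   `$paired` (per speed), `$curves` (list of pooled curves).
#' @export
analyze_psycho <- function(trials, speeds = NULL, n_bins = 8) {
  assert_columns(trials, c("subject_id", "speed", "contrast", "correct",
                           "rt", "prompted"), "trials")
  if (is.null(speeds)) speeds <- sort(unique(trials$speed))
  sens <- list(); curves <- list(); anovas <- list(); paired <- list()
  for (sp in speeds) {
    for (pol in c("light", "dark")) {
      acc <- build_accuracy_curve(trials, pol, n_bins, speed = sp)
      rtc <- tryCatch(build_rt_curve(trials, pol, n_bins, speed = sp),
                      onoffmotion_empty_curve = function(e) NULL)
      curves[[sprintf("acc_%s_%g", pol, sp)]] <- acc
      curves[[sprintf("rt_%s_%g", pol, sp)]] <- rtc
      s1 <- tryCatch(sensitivity_from_accuracy(acc),
                     onoffmotion_no_threshold = function(e) NULL)
      s2 <- if (!is.null(rtc)) {
        tryCatch(sensitivity_from_rt(rtc),
                 onoffmotion_no_threshold = function(e) NULL)
      }
      for (s in Filter(Negate(is.null), list(s1, s2))) {
        sens[[length(sens) + 1L]] <- data.frame(
          speed = sp, polarity = pol, criterion = s$criterion,
          threshold_contrast = s$threshold_contrast,
          sensitivity = s$sensitivity
        )
      }
    }
    acc_tab <- binned_by_subject(trials, "accuracy", n_bins, speed = sp)
    anovas[[sprintf("accuracy_%g", sp)]] <-
      c(list(speed = sp, measure = "accuracy"),
        polarity_anova(acc_tab, "accuracy")[c("F", "df1", "df2", "p")])
    rt_tab <- binned_by_subject(trials, "rt", n_bins, speed = sp)
    if (!is.null(rt_tab) && length(unique(rt_tab$polarity)) == 2L) {
      anovas[[sprintf("rt_%g", sp)]] <-
        c(list(speed = sp, measure = "rt"),
          polarity_anova(rt_tab, "rt")[c("F", "df1", "df2", "p")])
    }
    # paired test on per-subject mean accuracy
    sub <- trials[trials$speed == sp, , drop = FALSE]
    by_subj <- function(pol) {
      rows <- polarity_rows(sub, pol)
      tapply(sub$correct[rows], sub$subject_id[rows], mean)
    }
    l <- by_subj("light"); d <- by_subj("dark")
    common <- intersect(names(l), names(d))
    if (length(common) >= 2L) {
      paired[[sprintf("accuracy_%g", sp)]] <-
        c(list(speed = sp, measure = "accuracy"),
          paired_polarity_test(as.numeric(l[common]), as.numeric(d[common])))
    }
  }
  structure(
    list(sensitivity = do.call(rbind, sens), anova = anovas,
         paired = paired, curves = curves),
    class = "psycho_analysis"
  )
}

#' @export
print.psycho_analysis <- function(x, ...) {
  cat("2AFC motion-direction analysis\n\nContrast sensitivity:\n")
  print.data.frame(
    transform(x$sensitivity,
              threshold_contrast = signif(threshold_contrast, 4),
              sensitivity = signif(sensitivity, 4)),
    row.names = FALSE)
  cat("\nPolarity comparisons:\n")
  for (a in x$anova) {
    cat(sprintf("  %s @ %g deg/s: F(%d, %d) = %.2f, p = %.3g\n",
                a$measure, a$speed, a$df1, a$df2, a$F, a$p))
  }
  for (p in x$paired) {
    cat(sprintf("  paired %s @ %g deg/s: t(%d) = %.2f, p = %.3g\n",
                p$measure, p$speed, p$df, p$t, p$p))
  }
  invisible(x)
}

#' @export
plot.psycho_analysis <- function(x, speed = NULL, ...) {
  sp <- if (is.null(speed)) x$sensitivity$speed[1L] else speed
  acc_l <- x$curves[[sprintf("acc_light_%g", sp)]]
  acc_d <- x$curves[[sprintf("acc_dark_%g", sp)]]
  graphics::plot(acc_l$bin_centers, acc_l$values, type = "b", col = "red",
                 pch = 19, ylim = c(0.4, 1), xlab = "contrast magnitude",
                 ylab = "proportion correct",
                 main = sprintf("%g deg/s", sp), ...)
  graphics::lines(acc_d$bin_centers, acc_d$values, type = "b", col = "blue",
                  pch = 19)
  graphics::abline(h = 0.75, lty = 3)
  graphics::legend("bottomright", c("light", "dark"), col = c("red", "blue"),
                   pch = 19, bty = "n")
  invisible(x)
}
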