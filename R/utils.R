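# Internal helpers shared across the model and the two analysis pipelines.

#' Stop with a classed condition
#'
#' All errors raised by the package carry a subclass of `"onoffmotion_error"`
#' so callers (and the bootstrap machinery) can distinguish, e.g., a missing
#' level crossing from a genuine bug.
#' @noRd
stop_onoff <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "onoffmotion_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' First rising-edge crossing of a level
#'
#' Returns the earliest time at which `values` crosses `level` from below,
#' linearly interpolated between the two bracketing samples. The earliest
#' sample already at or above `level` defines the bracket; if it is the very
#' first sample the trace starts above the level and no rising edge exists.
#'
#' @param times,values numeric vectors of equal length, `times` increasing.
#' @param level the level to cross.
#' @return crossing time (scalar).
#' @noRd
first_rising_crossing <- function(times, values, level) {
  if (!any(is.finite(values))) {
    stop_onoff("trace contains no finite values", "onoffmotion_no_crossing")
  }
  idx <- which(values >= level)
  if (length(idx) == 0L) {
    stop_onoff(
      sprintf("trace never reaches level %.6g", level),
      "onoffmotion_no_crossing"
    )
  }
  i <- idx[1L]
  if (i == 1L) {
    stop_onoff(
      "trace starts at or above the level; no rising edge to interpolate",
      "onoffmotion_no_crossing"
    )
  }
  v0 <- values[i - 1L]
  v1 <- values[i]
  # v0 < level <= v1 by construction of i
  times[i - 1L] + (level - v0) / (v1 - v0) * (times[i] - times[i - 1L])
}

#' @noRd
assert_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_onoff(sprintf("`%s` must be a positive finite scalar", name),
               "onoffmotion_invalid_parameter")
  }
  invisible(x)
}

#' @noRd
assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_onoff(
      sprintf("`%s` is missing required column(s): %s",
              name, paste(missing, collapse = ", ")),
      "onoffmotion_invalid_input"
    )
  }
  invisible(df)
}
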