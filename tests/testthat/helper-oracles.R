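# Closed-form oracles used across tests.

# Rising-edge crossing time of a Gaussian bump peak * exp(-(t-center)^2/(2 sigma^2))
# through `level` (level < peak): center - sigma * sqrt(2 * log(peak / level)).
gauss_rising_crossing <- function(peak, center, sigma, level) {
  center - sigma * sqrt(2 * log(peak / level))
}

# A sampled Gaussian response on a uniform grid.
gauss_trace <- function(times, peak, center, sigma) {
  peak * exp(-(times - center)^2 / (2 * sigma^2))
}

# Hand evaluation of the Naka-Rushton scalar (kept separate from the package
# implementation on purpose).
nr_scalar <- function(s, r_max, l_50, n, th = 1) {
  (r_max * s^n / (l_50^n + s^n))^th
}
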