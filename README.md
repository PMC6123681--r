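# onoffmotion

Visual systems process light and dark through parallel ON and OFF pathways.
Dark responses are stronger, and stationary dark flashes are detected faster
than light ones — yet for *slowly moving* bars the ordering flips: cortical
responses and human reactions to lights lead those to darks, an advantage
that fades (and can reverse) as speed rises. `onoffmotion` packages the three
computational pieces needed to study this switch, for visual neuroscientists
and psychophysicists who want a tested, seedable reference implementation:

- **A forward latency model.** The drive at a receptive-field center is a
  Gaussian in time with FWHM = bar width / speed, passed pointwise through
  ON/OFF Naka-Rushton luminance-response functions with a power-function
  spike threshold:

  R(t) = ( R_max · s(t)^n / (L50^n + s(t)^n) )^th

  with ON (R_max 80, L50 0.4, n 1.4) below OFF (100, 0.5, 2.3) and th rising
  with speed (1.0 at 5 deg/s to 3.5 at 60 deg/s). Latency is read at half
  the peak of the weaker (light) response.
- **An electrophysiology pipeline** (`analyze_psth()`): 35-bin PSTHs per
  direction/polarity/speed, Gaussian smoothing (sd 1 bin, edge-renormalized),
  direction-selectivity filtering (DSI = (R_pref − R_opp)/R_pref, keep
  DSI > 0.25), Gaussian-plus-line peak alignment per site, averaging over
  sites, half-amplitude dark-minus-light latency differences, and 200-sample
  site-level percentile bootstrap CIs.
- **A psychophysics pipeline** (`analyze_psycho()`): accuracy and
  reaction-time psychometric functions versus contrast magnitude from 2AFC
  motion trials (prompted trials count toward accuracy, never RT), contrast
  sensitivity as the reciprocal of the contrast at proportion correct 0.75
  or at the RT halfway point, polarity ANOVAs, and paired t tests.
- **Synthetic-data generators** (`generate_spike_tables()`,
  `generate_trial_table()`): seeded, bit-reproducible spike-event and trial
  tables with known ground truth, so every stage of both pipelines is
  testable end to end.

## Worked example

Simulate the model at its defaults:

```r
library(onoffmotion)
simulate_latency_difference()
#> ON/OFF latency model: dark-minus-light latency differences
#>
#>  speed_deg_s  th latency_light_ms latency_dark_ms difference_ms
#>         5.00 1.0         -279.903        -256.562        23.341
#>        10.00 2.0         -110.129        -112.303        -2.174
#>        16.15 2.5          -62.785         -67.051        -4.266
#>        30.00 3.0          -31.525         -35.126        -3.601
#>        60.00 3.5          -14.838         -17.194        -2.356
```

At 5 deg/s the dark response lags the light response by 23 ms (positive
difference: lights lead), because the more sensitive, more saturated ON
function broadens the light response and it reaches the half-amplitude
criterion first. From 10 deg/s up, the rising spike threshold hands the
advantage to the stronger dark response: differences turn slightly negative
and shrink toward zero as the stimulus gets briefer. Latencies are measured
from the stimulus center, so the negative values simply mean the criterion
is crossed on the rising flank before the peak.

Recover a known latency difference from synthetic recordings:

```r
spec <- site_population_spec(n_sites = 30, speeds = 5,
                             true_latency_difference = c(`5` = 0.015),
                             seed = 3002)
spikes <- generate_spike_tables(spec)   # 30 sites x 16 directions x 2 polarities x 4 sweeps
analyze_psth(spikes, n_boot = 200, seed = 2)
#> Cortical light/dark latency differences (half-amplitude criterion)
#> Sites: 30 analyzed, 0 excluded by the DSI > 0.25 filter
#>
#>  speed_deg_s n_sites latency_light_ms latency_dark_ms difference_ms ci_low_ms ci_high_ms
#>            5      30          -891.39         -881.59           9.8      -8.5      25.09
```

The point estimate (9.8 ms) is a noisy but honest read of the injected
15 ms difference — four sweeps of Poisson spiking at ~60 spikes/s is a hard
measurement — and the 95% bootstrap CI covers the truth. The test suite
verifies that over 50 replicate populations the CI covers the injected value
at least 90% of the time.

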