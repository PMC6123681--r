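---
title: "Methods: modelling and measuring ON/OFF latency asymmetries for moving stimuli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and measuring ON/OFF latency asymmetries for moving stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onoffmotion)
```

## The scientific problem

Mammalian vision splits luminance processing at the first retinal synapse into
an ON pathway that signals luminance increments and an OFF pathway that
signals decrements. OFF-dominated responses are stronger, and for stationary
flashed stimuli darks are detected faster and more accurately than lights.
For *moving* stimuli this can invert: responses to slowly moving light bars
lead responses to dark bars, and the advantage fades (and can reverse) as
speed rises. This package implements the three computational pieces needed to
study that switch at desk scale: a forward latency model, a cortical
spike-train analysis chain, and a psychophysics analysis chain, plus seeded
generators that produce synthetic recordings and trial tables with the
statistical structure those chains assume.

## The forward latency model

The drive at a receptive-field center while a bar of width $w$ sweeps past at
speed $v$ is modelled as a Gaussian in time whose full width at half maximum
is the transit time,

$$\mathrm{FWHM} = w / v, \qquad \sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2}),$$

so doubling the speed halves the width. The drive $s(t) \in [0, 1]$ is passed
pointwise through a Naka-Rushton luminance-response function with a
power-function spike threshold:

$$R(t) = \left( R_{max} \, \frac{s(t)^n}{L_{50}^n + s(t)^n} \right)^{th}.$$

The ON (light-response) parameters sit strictly below their OFF counterparts:
$R_{max}$ 80 vs 100 (light responses 20% weaker, matching cortical
measurements), $L_{50}$ 0.4 vs 0.5 (ON is more contrast-sensitive), $n$ 1.4
vs 2.3 (ON saturates more gradually). The threshold exponent increases with
speed (5 deg/s: 1.0, 10: 2.0, 16.15: 2.5, 30: 3.0, 60: 3.5). Latency is read
out where the rising edge crosses half the peak of the lower-amplitude
response — the light response under the defaults — so the same absolute level
is applied to both polarities, exactly as in the cortical measurements.
Latencies are reported relative to the stimulus center, which makes them
independent of the simulation window.

Two opposing forces set the sign of the dark-minus-light difference. The ON
pathway's higher sensitivity and stronger saturation make the light response
*broader*, so it reaches the shared level earlier — lights lead. The OFF
pathway's larger amplitude makes the dark response cross the (light-referenced)
level relatively earlier — darks lead. Both effects scale with the stimulus
width $\sigma \propto 1/v$, while the threshold exponent reweights them:
at 5 deg/s ($th = 1$, wide stimulus) the width effect dominates and the
difference is large and positive; at 10 deg/s and beyond the rising threshold
hands the advantage to amplitude and the difference becomes small and
negative, shrinking in magnitude toward zero as $\sigma$ shrinks. Because the
difference factors as $\sigma(v) \cdot k(th)$, this late shrinkage toward
zero is forced by the printed parameters: the sequence over the five standard
speeds is not globally monotone, but drops steeply and then converges to
zero. With $th \equiv 1$ at all speeds the difference stays positive and
decays monotonically like $1/v$, which is why the threshold is not needed for
the convergence itself — only for the sharp drop at 10 deg/s.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `bar_width` | 2.1 | deg | the physiology bar |
| `peak` | 1.0 | fraction of full excursion | near-full-contrast bars on mid-gray |
| `dt` | 1 ms (0.1 ms at ≥ 30 deg/s) | s | high-speed differences are sub-millisecond |
| `reference` | `"lower"` | — | equals "peak of the light response" under defaults; `"light"` exposed |
| `n_sigma` | 5 | σ | window comfortably covers the rising flank |

Crossings are located by linear interpolation between the two bracketing
samples of the earliest rising edge; halving `dt` moves any reported latency
difference by less than `dt` (this is asserted by a test). Ties cannot occur
on a strictly rising flank; for multimodal inputs the first crossing wins.
The threshold is the outer power exponent exactly as written above, not a
subtractive floor.

## The cortical analysis chain

`analyze_psth()` consumes a spike-event table (site, direction, polarity,
speed, sweep, spike time) and proceeds:

1. **Binning.** Spikes are counted into 35 equal-width half-open bins
   spanning one sweep (`screen_traverse / speed` seconds), summed over the 4
   sweeps; out-of-window spikes are dropped and counted. Sweeps at 15 and
   17.3 deg/s give closely similar responses and are pooled bin-wise (bins
   correspond after normalizing time to the sweep), labeled 16.15 deg/s.
2. **Smoothing.** Rates are smoothed with a discrete Gaussian kernel of sd
   1 bin, truncated at ±4σ and renormalized to unit sum at every position,
   so constants pass through unchanged and total mass is conserved at the
   edges.
3. **Direction selectivity.** Light and dark responses are summed per
   direction *before* smoothing, the maximum smoothed rate per direction is
   the direction's response $R$, and
   $DSI = (R_{pref} - R_{opp}) / R_{pref}$. Sites with $DSI \le 0.25$
   (strict inequality retains) are excluded. Ties in the preferred direction
   resolve to the lowest direction index. The DSI here is pooled over speeds
   (per-direction counts summed across speeds on the normalized bin grid),
   giving each site one preferred direction used at every speed.
4. **Alignment.** Receptive fields sit at slightly different screen
   positions, so responses peak at different times. A Gaussian-plus-line
   model $a\,e^{-(t-\mu)^2/(2w^2)} + bt + c$ is fitted
   (Levenberg-Marquardt with box bounds; initialization: $a$ from the data
   range, $\mu$ at the maximum bin, $w$ = span/10, line seeded from the
   first and last quartiles of bins; $w$ bounded in (bin/2, span), $\mu$
   inside the sweep) to the light+dark combined preferred-direction time
   course, and the *same* fitted peak time shifts both polarities. A
   per-polarity shift would subtract out the very latency difference being
   measured. Fit failures exclude the site from averaging and are counted.
5. **Averaging and latency.** Shifted traces (sub-bin shifts by linear
   interpolation onto a common grid at the native bin width) are averaged
   over sites per polarity; the dark-minus-light latency difference is read
   at half the peak of the lower-amplitude mean.
6. **Bootstrap.** Sites are the resampling unit: 200 subsamples drawn with
   replacement, the average and the latency difference recomputed per
   replicate, and the 95% CI taken as the 2.5th/97.5th percentiles.
   Replicates without a level crossing are dropped and counted; more than
   20% failures aborts as unstable. The percentile method (not BCa) keeps
   the procedure simple and deterministic under a single seed.

## The psychophysics chain

`analyze_psycho()` consumes 2AFC motion-direction trials with signed
contrasts ($(L_{stim} - L_{bg})/L_{bg}$, negative = dark). Accuracy curves
use equal-count (quantile) contrast-magnitude bins, 8 by default, and include
prompted trials (responses given after the 1 s deadline lapsed); RT curves
exclude prompted trials and average unprompted reaction times per bin
(mean by default, median exposed), which is why they start at higher
contrasts. Contrast sensitivity is the reciprocal of the threshold contrast:
at proportion correct 0.75 (linear interpolation between bracketing bins of
the across-subject pooled curve), or at the reaction time halfway between the
pooled curve's highest and lowest values, approached from the high-RT side.
No parametric psychometric function is imposed anywhere.

The polarity comparisons follow two routes. The ANOVA is an OLS linear model
on per-subject binned curves weighted by bin counts — subject and polarity as
factors plus powers of contrast magnitude 1–4 for accuracy, contrast and its
square for RT, speed and its square for sensitivity — with the polarity F
from a nested-model (Type II) comparison in which interactions involving
polarity are excluded from both models. Curve-level observations (6 subjects
× 2 polarities × 5 bins) match the residual degrees of freedom this design
implies. The paired t test compares per-subject light and dark values
two-sided; zero-variance differences are reported explicitly as degenerate
rather than erroring.

## What the generators emulate — and what they do not

`generate_spike_tables()` draws spikes from inhomogeneous Poisson processes
(thinning). Each site gets a preferred direction, a DSI from a truncated
normal (mean 0.6, sd 0.15), and a receptive-field time offset (normal,
sd 0.2 s, clamped to ±30% of the sweep). Direction tuning is von-Mises
shaped, $g(\theta) = \exp(\kappa(\cos(\theta - \theta_{pref}) - 1))$ with
$\kappa = -\log(1 - DSI)/2$, so the noiseless DSI equals the drawn value
exactly. The light rate is the ON-pathway Naka-Rushton transform of the
stimulus (peak ≈ 63 spikes/s) over a 2 spikes/s baseline; the dark rate is
the same shape scaled by 1/0.8 and time-shifted. The response FWHM is
`(bar_width + rf_width)/speed` with a 4-deg receptive field, so the response
spans several of the 35 bins at low speed.

The ground-truth latency difference is defined as the half-amplitude
difference of the noiseless traces *at the pipeline's measurement
resolution*: 35-bin binning, 1-bin smoothing, and re-gridding at an arbitrary
sub-bin phase each displace the interpolated crossings by systematic amounts
that do not average away with more sweeps or sites, so the dark shift is
solved numerically (against the phase-averaged alignment/averaging/crossing
machinery itself) until the measured noiseless difference equals the
requested value. Without this, "recover the injected difference" would be an
ill-posed target.

`generate_trial_table()` samples signed contrasts from a zero-mean Gaussian
(sd 0.08), directions with probability ½, correctness from a cumulative
Gaussian in log contrast,
$P(correct \mid c) = 0.5 + (0.5 - \lambda)\,\Phi(\beta \log(|c|/c_{50}))$,
and reaction times from $(t_0 + k\,c_{50}/|c|)\,e^{\epsilon}$ with lognormal
noise, censored at the 1 s deadline (censored trials are prompted: they count
toward accuracy, never RT). The psychometric link and the hyperbolic RT law
are generator choices, not empirical claims, and are configurable. Default
$c_{50}$ values make lights more sensitive at low speeds (0.020 vs 0.032 at
1 deg/s) with the gap closing by 30 deg/s (0.060 vs 0.065), and six subjects
are simulated; trial counts are set for statistical power, not fidelity to
any particular experiment.

Neither generator attempts cortical dynamics beyond rate-modulated Poisson
statistics, receptive-field spatial structure, adaptation, eye movements, or
sequential dependencies between trials. Passing round-trip tests therefore
shows that the estimators are consistent and honestly calibrated for data
with this statistical structure — not that real recordings satisfy that
structure.

## Problem sizes used by the test suite

The coverage study runs 50 replicate populations of 30 sites × 4 sweeps at
5 deg/s with a 15 ms injected difference and 200 bootstrap subsamples each;
the statistics calibration runs 1000 polarity-null experiments of 6 subjects
× 120 trials, checking that the ANOVA and the paired t test reject at
0.05 ± 0.02. Model identities are checked analytically (half-saturation to
1e-9 relative error; Gaussian crossings against closed forms).

## Known limitations

- The model is a pointwise static nonlinearity: no spiking dynamics, no
  spatial receptive-field structure, no retinal or geniculate circuitry.
- Absolute simulated latencies depend on the width convention
  (FWHM = width/speed); any fixed proportionality rescales all latencies
  jointly, preserving signs and ordering but not absolute milliseconds.
- The half-amplitude latency difference deliberately conflates response
  timing, width, and amplitude — that is the measured quantity, not a pure
  conduction delay.
- Percentile bootstrap CIs on 30 sites are honest but wide; the recovery
  criterion is coverage, not precision.
- The DSI pooling across speeds, the light+dark summation before smoothing,
  and the 15/17.3 deg/s pooling mechanics are reasonable choices where the
  measurement conventions are underdetermined; all are isolated behind
  single functions with their own tests.
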