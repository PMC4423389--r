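---
title: "Harmonizing irregular lake surface temperature records into seasonal means"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing irregular lake surface temperature records into seasonal means}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laketherm)
```

## The problem

Long-term lake surface water temperature records come from monitoring
programs with wildly different protocols -- weekly profiles, monthly grab
samples, continuous buoys, nighttime thermal-infrared satellite overpasses --
and from lakes in both hemispheres and the tropics. To compare warming
across lakes, each lake-year must be reduced to a single comparable
statistic. `laketherm` implements a harmonization pipeline that produces
3-month "summer" mean surface temperatures from either kind of record,
quantifies the error that sparse sampling introduces, and cross-validates
the two observation platforms.

## Seasonal windows

Summer is fixed by latitude: July--September (JAS) in the extratropical
Northern Hemisphere, January--March (JFM) in the extratropical Southern
Hemisphere. Within the tropics (|lat| < 23.5&deg;) the assignment is flipped
-- JAS south of the equator, JFM north of it -- so that the window targets
the dry season, where cloud-free satellite retrievals are plentiful. Winter
is the opposite 3-month block. Per-site overrides (e.g. JJA for high-arctic
lakes that freeze before September) take precedence.

Two boundary conventions are deliberate choices, because any convention
works as long as it is deterministic: latitude exactly 0 is treated as
northern tropical (JFM), and |lat| exactly 23.5 as extratropical. For an
override window that wraps the calendar year (winter DJF opposite a JJA
summer) the window is labeled by the calendar year of its first month, so
DJF 2000 runs 1 December 2000 -- 28 February 2001. All dates are
timezone-free calendar dates; a JAS grid always has 92 days, JFM 90 or 91.

## In situ means: interpolation

Within a lake-year, observations (deduplicated to daily means when a day
has several) are connected by straight chords and evaluated on every day of
the window; the seasonal mean is the arithmetic mean of those daily values.
Observations just outside the window may anchor the chord across the
boundary. The minimum to attempt a mean is two in-window observations
(configurable); below that the lake-year is flagged `insufficient_data`
rather than guessed.

### What sparse sampling does: the chord bias

On a curved seasonal trajectory the chord lies below a concave curve, so
interpolation *underestimates* the summer mean. For a quadratic trajectory
with second-derivative `2a` (`a < 0` at a summer peak) sampled every `h`
days, the continuous time-average of (interpolant - truth) over any whole
number of sampling intervals is exactly

> bias = a h^2 / 6.

`interpolation_bias()` computes that continuous average by per-segment
Simpson quadrature (exact for quadratic truths), and the package's tests
verify the closed form to 1e-6 &deg;C for h from 2 to 46 days. Two discrete
variants are worth recording because they differ: averaging on the *daily
grid* (what the pipeline itself does) gives `a (h^2 - 1) / 6` when the
window tiles into whole intervals, and the same value is obtained when the
sampling phase is averaged uniformly. At h = 30 days and a realistic
curvature of 0.0025 &deg;C/day^2 both forms are about -0.37 &deg;C -- a few
tenths of a degree, which is why monthly sampling remains usable.

## In situ means: parabolic extrapolation of truncated seasons

Some programs stop sampling before the window closes (early freeze-up) or
start late. For those lake-years the site's *pooled* multi-year record --
all observations for that site and depth, indexed by day-of-year (DoY) --
is fitted by ordinary least squares to

> temperature = a DoY^2 + b DoY + c,

a generic representation of the site's seasonal cycle. The fitted curve is
then shifted vertically (only `c` changes) to pass exactly through the
first sample of the truncated year (for a missing start) or the last sample
(missing end); daily values for the uncovered part of the grid are read off
the shifted curve. The two sides shift independently, and each side is
recorded in a processing-log entry carrying the equation, the period
covered, and the pooled fit's R-squared. Numerical conventions: R-squared
is computed about the mean of the pooled points and defined as 1 when the
total sum of squares is zero (constant data fitted perfectly); convex
pooled fits (`a >= 0`) are used as-is; DoY comes from the actual calendar,
so pooling across leap and non-leap years carries a one-day phase drift
that is accepted; fits require at least three distinct DoY values. When a
year needs both sides extrapolated, one log entry per side is written,
since a single entry could not carry the two distinct shifted intercepts.

## Satellite means

Nighttime thermal-infrared retrievals pass three screens before smoothing:

* **View zenith**: retrievals acquired at zenith angles above 45&deg; are
  discarded (exactly 45&deg; is kept) -- long atmospheric paths degrade the
  retrieval.
* **Spatial homogeneity**: a 3x3 pixel array whose standard deviation
  exceeds 0.5 &deg;C indicates partial cloud or land in the array and is
  dropped. The SD is the sample SD (n-1 denominator; configurable to
  population), the comparison is strict (`> 0.5` drops, `= 0.5` keeps), and
  arrays with any missing pixel are dropped conservatively. Degenerate 1x1
  center-pixel products carry no spatial information and skip this test;
  their cloud screening lives upstream in the source product.
* **Skin-to-bulk**: radiometers sense the sub-millimeter skin, cooler at
  night than the ~1 m bulk temperature that in situ programs report. A
  sensor-specific linear correction `bulk = slope * T + intercept` maps
  skin to bulk; the numeric factors are calibration products supplied
  through configuration, not hard-coded.

Screened series from different sensors are merged into one date-sorted
record (same-date retrievals from two sensors both count), maximizing the
sampling frequency.

Each calendar year is then smoothed with Cleveland's robust LOWESS
(tricube-weighted local linear regression, iterated bisquare reweighting,
via `stats::lowess`), and the seasonal mean is the average of the smoothed
curve over the window grid. A mean is only emitted when at least 20 valid
in-window retrievals exist (`min_retrievals`, configurable) -- fewer cannot
characterize the temperature curve.

### Smoother tuning, and two stability guards

The span (fraction of the year's points per local fit) matters more than
any other tunable. Local linear smoothing carries a curvature bias of
roughly `-f'' * sigma_w^2 / 2` for local-window spread `sigma_w`; fitting a
full annual cycle (winter troughs to summer peak) with a wide span flattens
the peak and biases the summer mean cold. Measured on the package's own
sinusoidal generator with ~500 nightly retrievals in a year: span 0.4 gives
about -1.0 &deg;C seasonal-mean bias, span 0.1 about -0.09 &deg;C. The
default is therefore `span = 0.1` -- a roughly month-scale local window for
dense nightly sampling -- with everything configurable per analysis.

Two numerical guards stabilize edge cases. First, sparse years are fitted
with a floor of 15 points per local window: with windows much smaller than
that, the bisquare reweighting can fail to outvote a single outlying
retrieval (at a 7-point window a +10 &deg;C spike among 50 clean points is
*reproduced* by the robust fit). Second, when the initial fit already
interpolates the data (residual MAD below 1e-9 of the data range), the
robust iterations are skipped entirely: `lowess`'s bisquare weights divide
by the residual MAD and degenerate when it is numerically zero, which would
otherwise break exactness on noiseless linear data. Evaluation between
fitted points is linear, and beyond the observed date range the nearest
fitted value is carried flat -- deliberately conservative, with the caveat
that a window reaching far outside the observed dates inherits that flat
tail.

## Radiation

Total incoming radiation absorbed by a dark, ice-free water surface is

> R_tot = 0.93 SW + 0.97 LW

(shortwave albedo 7%, longwave emissivity 0.97), applied wherever both the
seasonal shortwave and longwave records exist.

## Gap-error bootstrap

To relate sampling interval to seasonal-mean error, the pipeline subsamples
a daily record: for each interval h (1 to 34 days by default) it draws a
first sample date uniformly at random in the calendar month preceding the
window (June for JAS), samples every h days from there, recomputes the
interpolated seasonal mean, and scores it against the interval-1 ("true")
mean. Errors are signed (estimate minus truth); interval 1 has zero error
by construction. Since replicate variation is driven *only* by the start
date, the randomization space has just 28--31 points, and the package
exposes an exact enumeration mode (equal weight on every start date) as the
reference against which Monte Carlo runs must converge. The Monte Carlo
default is 2,000 replicates per interval -- the enumeration mode makes more
replicates a convergence exercise rather than new information; 20,000 is
available by argument.

## Cross-platform validation

For lakes with both satellite and in situ series, three RMSEs are computed
over their temporally matched years (years where both platforms report):
of the means (pooled across all lake-year pairs), of the anomalies (each
matched series minus its own baseline-period mean, baseline 1985--2009
restricted to matched years), and of the per-lake linear trend differences
(OLS slope on calendar year by default; Theil--Sen optional, with a 3-year
floor). The algebra to note: a constant per-lake offset between the
platforms -- the signature of residual skin-bulk or day-night sampling
differences -- inflates only the RMSE of means; anomalies and trends are
exactly invariant to it. That is why platform comparisons improve markedly
when moving from raw means to anomalies. Matching the years before taking
baselines and trends is what makes the invariance exact; computing each
platform's baseline over its own (different) year set would leak offset
into the anomalies.

## The synthetic generator: what it does and does not emulate

Every stage is testable without downloads via seeded generators:

* `synth_daily_series()` -- a daily "true" curve plus noisy observations.
  Two families: *parabolic* (quadratic around the summer peak; exact
  closed-form biases, but a within-season model only -- it diverges far
  from the peak) and *sinusoidal* (annual harmonic; the realistic choice
  for full-year satellite simulations). Defaults are temperate-lake
  magnitudes: peak 24 &deg;C at DoY 215, curvature 0.0025 &deg;C/day^2,
  semi-amplitude 9 &deg;C, noise SD 0.5 &deg;C. The generator returns the
  noiseless truth and its exact window means, defined as the mean of the
  noiseless daily values over the window grid -- the pipeline's actual
  estimand (the continuous integral differs from it at order curvature/12,
  about 2e-4 &deg;C).
* `synth_insitu_sampling()` -- cadence, jitter, dropout, and truncation
  (to force the extrapolation path).
* `synth_satellite_retrievals()` -- nightly candidates per active sensor,
  cloud dropout, bulk-minus-skin offset with nightly noise, per-pixel
  array noise, uniform zenith angles, and contaminated arrays built from an
  alternating +/-2 &deg;C pattern whose SD (~2.1 &deg;C) deterministically
  fails the homogeneity test.

Not emulated: autocorrelated weather-driven noise (hook documented, not
default), diurnal cycles, ice phenology, sensor drift, or physically based
heat budgets. Passing tests on these generators therefore demonstrate the
*estimators'* correctness and the pipeline's plumbing, not that any real
lake meets the generators' assumptions.

## Problem sizes and test design

The suite verifies the in situ mean against an independent brute-force
piecewise-linear oracle on 100 random series (tolerance 1e-9 &deg;C), the
chord-bias closed form at five sampling intervals, the gap-error bootstrap
at 2,000 Monte Carlo replicates per interval against the 30-date
enumeration, and parabola coefficient recovery over 500 replicates of
n = 200 noisy fits (each coefficient inside its 95% confidence band at
least 90% of the time). These sizes make the full suite run in a few
seconds while leaving every Monte Carlo comparison inside 3 standard
errors of its exact reference.

## Known limitations

* The skin-to-bulk factors and LOWESS tuning of any particular archived
  satellite product are calibration inputs; the package ships the
  machinery, not the numbers.
* Extrapolation inherits the pooled parabola's shape; a year whose season
  genuinely differed in shape (not level) from the site's climatology is
  extended with the wrong curvature, and only the log's R-squared hints at
  it.
* Gap statistics count only between-sample gaps inside the window, so a
  season sampled twice, at day 1 and day 92, reports a single 91-day gap
  and no boundary distances.
* The wide-format values exporter densifies sparse archives; the long
  format is the canonical representation.
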