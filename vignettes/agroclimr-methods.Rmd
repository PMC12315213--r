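---
title: "Models and methods in agroclimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in agroclimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agroclimr)
```

agroclimr assembles the family of "direct risk" models used to screen
climate-change impacts on temperate (New Zealand-style) agriculture from
daily gridded weather: threshold-exceedance crop hazards, degree-day
phenology with a maturity-failure metric, a staged soil-water balance
accumulating potential evapotranspiration deficit (PED), fuzzy-logic crop
suitability, empirical animal-health indices, and time-slice/ensemble
aggregation. This vignette documents each model, its assumptions and
tunable parameters, the synthetic weather generator that drives the test
suite, and the numerical conventions adopted where the design was open.

## The synthetic weather generator

Real assessments of this kind run on multi-decadal daily series downscaled
from an ensemble of global climate models onto a ~5 km national grid. Those
archives are terabytes and not redistributable, so the package ships a
stochastic generator whose output has the same shape and the statistical
features the downstream models actually consume:

* **Temperature.** A cell-specific annual sinusoid (mean `temp_mean`,
  half-range `temp_amplitude`, peak in mid-January for southern-hemisphere
  latitudes) plus a first-order autoregressive daily anomaly
  (`ar1 = 0.7`, innovation s.d. `noise_sd = 2` degC by default — typical
  day-to-day persistence for mid-latitude station records). `tmin` and
  `tmax` share the anomaly and are separated by a positive diurnal range
  (mean 8 degC, floored at 0.5 degC), so `tmax >= tmin` holds by
  construction rather than by rejection.
* **Precipitation.** The classic WGEN structure: two-state first-order
  Markov occurrence (`p_dry_wet = 0.25`, `p_wet_wet = 0.6`, stationary
  wet-day frequency `p01/(1 + p01 - p11)` ≈ 0.38) with gamma wet-day
  amounts (shape 0.8, scale 8 mm, i.e. ≈ 900 mm/yr), values in the range
  of lowland New Zealand climates.
* **Radiation, humidity, wind.** Climatological sinusoid (radiation) or
  constant mean (humidity, wind) plus Gaussian noise, clipped to physical
  ranges. Cross-correlation with rainfall (cloudy days are wetter and
  dimmer) is deliberately omitted; tests that depend on ET therefore
  slightly overstate radiation on wet days.
* **Scenarios.** A `scenario_perturbation` adds a warming offset to both
  temperature fields — ramped linearly from zero at the series start to its
  full value at the end by default, so that 20-year time slices cut from
  one transient run genuinely differ — and scales precipitation amounts
  multiplicatively. The bundled `rcp_perturbations()` end-of-century
  offsets (+0.7/+1.4/+1.8/+3.0 degC, precipitation × 1.00–1.05) are
  mid-latitude-representative settings chosen once for the synthetic
  experiments; they are generator conventions, not downscaled model output.
* **Ensemble members** differ only by their random stream (a 31-bit seed
  derived from the base seed, cell index and member id). This reproduces
  internal variability but *not* inter-model structural spread; cross-member
  spread in synthetic experiments is therefore narrower than a true
  multi-model ensemble's.

Perturbations are applied after the random draws, so a perturbed series is
day-by-day comparable with its baseline. That enables the paired
experiments used throughout the tests: warming a series can only add heat
days, remove frost days, and advance phenology, so directional claims can
be asserted deterministically. What passing those tests shows is that each
model transforms a warming signal in the physically required direction —
not that synthetic magnitudes match any real region.

The calendar is the real proleptic calendar with leap days; hazard windows
ending on 29 February resolve to 28 February in non-leap years.

## Hazard indices

`builtin_hazard_specs()` carries eleven crop-hazard rules (heat stress,
frost, extreme rainfall for six arable crops), each a sensitive month-day
window, a daily variable and a strict threshold. Comparisons are strict
(`>` / `<`) exactly as the thresholds are conventionally printed, while
the rainfall rule's daily qualifier is inclusive (≥ 5 mm/day): a window
triggers when some 7-day span lying *wholly inside* the window contains
strictly more than 3 qualifying days. Requiring containment (rather than
anchoring spans that may leak outside the window) differs from the
alternative only at window edges; it was chosen because the window is
defined as the crop's sensitive period, and damage outside it is not the
hazard being counted.

Cross-year windows (e.g. maize, 15 Dec–15 Feb) belong to the season of
their end date; partial first/last seasons of a series are dropped, never
padded. The change statistic is the arithmetic difference of per-cell mean
annual event-day counts (days/yr), with ratios available through the
aggregation module's proportional mode.

## Degree-day phenology

Daily thermal time uses the simple-average method
`max(0, min(Tmean, cutoff) - base)`; the default maize parameterisation
(base 8 degC, cutoff 30 degC, stage boundaries at 150/450/900/1350 degC·day,
stage Kc 0.3/0.75/1.2/0.5) is a conventional temperate maize-silage
setting in the FAO-56 spirit, *not* a published calibration — each value is
a function argument precisely so local calibrations can replace it. The
development-stage Kc (0.75) is the midpoint of the FAO initial and mid
coefficients, standing in for the within-stage interpolation a daily
crop model would use.

Seasons run 1 July to 30 June of the harvest year (southern-hemisphere
convention); the 30 June cutoff gives the maturity-failure metric a hard
end date. Sowing defaults to a fixed 1 October; a temperature-trigger rule
(first day after a given date whose trailing-window mean temperature
reaches a threshold) is provided because earlier sowing under warming is
exactly the adaptation experiment such screening studies discuss. A
trigger that never fires leaves the season unsown — a model outcome
counted as a failure, not an error.

The maturity-failure fraction over a 20-season slice is the share of
seasons in which accumulated thermal time never reaches the final
threshold. Under a warming perturbation this is non-increasing season by
season, which is the mechanism behind the "fewer failed crops in a warmer
climate" pattern the tests reproduce.

## Water balance and PED

Reference ET defaults to Priestley–Taylor (`alpha = 1.26`, net shortwave
`0.77 × radiation`, soil heat flux and net longwave neglected): it needs
only temperature and radiation, is monotone in both, and keeps the model
in the "simple FAO bucket" class. A simplified FAO-56 Penman–Monteith
(same net-radiation approximation, humidity and wind from the data model)
sits behind `method = "penman_monteith"` for sensitivity work; with the
longwave term omitted both variants run a little high on clear dry days.

The bucket is a single store of size `available_water_capacity`. Daily
demand is `Kc × ET0`; actual ET scales linearly once soil water falls
below `stress_f = 0.5` of capacity (the standard single-reservoir stress
response) and is additionally capped by the water physically present that
day, which is what makes the mass balance close to machine precision —
the conservation property the test suite checks over 10,000 random steps.
Excess above capacity drains instantly (no routing, no groundwater). The
store starts full on 1 July (winter-recharge assumption, configurable).
Unmet demand accumulates as PED.

Two accumulation windows are offered because "over the period of growth
and water demand" is genuinely ambiguous: `"growth"` (default) returns the
deficit accumulated from sowing to maturity; `"calendar"` continues to the
season cutoff with the final stage's coefficient, approximating a field
that still transpires after grain maturity (or a pasture-like cover). A
constant-Kc entry point (`run_water_balance()`) covers the classic
fixed-coefficient PED and pasture runs.

Monthly demand profiles sum daily demand per calendar month per
season-member trace; the demand-weighted centre (months since 1 July)
is the scalar used to detect the "peak water demand arrives earlier"
pattern.

## Fuzzy suitability

Memberships are trapezoids `a <= b <= c <= d` (0 outside `[a, d]`, 1 on
`[b, c]`, linear between): the minimal shape giving a plateau, linear
transitions, one-sided variants (via sentinel breakpoints) and a clean
discretisation. The default combiner is `min` — the limiting-factor
convention of land-evaluation practice — with `product` and weighted
geometric mean available because the published studies in this space do
not settle the choice. Class thresholds 0.25/0.5/0.75 (left-closed) are a
declared convention. The shipped apple/kiwifruit rule files are
illustrative, non-calibrated defaults that exercise the framework; real
assessments must supply crop-specific calibrated rules.

Attribute summaries (mean-annual GDD, frost days, heat days, rainfall) are
computed from the same primitives as the hazard and phenology modules, and
a test pins that consistency.

## Empirical animal-health risk

The occurrence model is a maximum-likelihood logistic regression of a
binary outcome on monthly mean temperature and monthly rainfall — the
structure of empirical facial-eczema (fungal sporulation) risk models; the
covariate builder is pluggable so the same machinery serves other
climate-driven diseases (e.g. Haemonchus risk) with a different covariate
file. Degenerate designs (one outcome class, separation, fewer than 30
records) are refused with the offending covariate named. Projection runs
the fitted linear predictor through the logistic link; covariates beyond
the training range widened by its own width on each side (a "3× range"
band) trigger an extrapolation warning but still return a value, since
screening future climates is precisely an extrapolation exercise that the
user must judge.

The dairy heat-stress index is the Davis-lineage temperature–humidity
index `THI = 0.8 T + RH/100 (T − 14.4) + 46.4` with exceedance threshold
68; both are arguments, as several THI variants circulate.

## Aggregation

All products funnel through one normative two-stage order: within-slice
statistic per ensemble member first (mean over years by default), then the
cross-member central value — the median, matching the usual
"median across models" map convention — with min/max spread and the full
member values retained. A property test pins this order against brute
force so it cannot silently swap. Change maps are absolute differences or
percentage changes; zero baselines are flagged undefined rather than
producing infinities. Slice windows are always explicit arguments because
published studies mix conventions (1981–2000, 1985–2005, 1972–2004 are
all in circulation).

## Problem sizes and determinism

The end-to-end pipeline (`run_pipeline()`) defaults to a 10 × 10-cell
grid, 40 years of daily weather and 3 ensemble members — about 4.4 million
cell-days — which a single core handles in a few minutes; the first and
last 20 years of the one transient run serve as its baseline and future
slices. Unit and property tests use single cells and 1–21-year series;
the qualitative-pattern tests use a 3 × 3 grid and 21 years with paired
warming offsets. Every random draw descends from one user seed, and
rerunning any product with the same seed reproduces it byte for byte.

## Known limitations

* Generator members share one statistical model: ensemble spread
  understates structural uncertainty.
* No cross-correlation between rain, radiation and humidity; no bias
  correction; no CO₂ fertilisation effect on development or water use.
* Single-bucket hydrology: no layered soil, runoff routing or irrigation
  scheduling beyond the unlimited-irrigation contrast.
* Default crop parameters and suitability rules are conventions for
  testing the machinery, not calibrations; conclusions about real places
  require real downscaled climate, soils and calibrated rule sets.
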