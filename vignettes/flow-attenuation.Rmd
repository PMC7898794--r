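---
title: "Quantifying flow attenuation from storm events: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying flow attenuation from storm events: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowatten)
```

## The problem

Ecosystem engineering — most prominently beaver dam complexes — can slow
the passage of storm water through a catchment: peak discharge drops, the
rainfall-to-peak lag grows, and the flow regime becomes less flashy, while
the total volume of water is merely delayed, not removed. Detecting and
attributing such *flow attenuation* from field records is a
before–after(–control–impact) problem: monitoring stations record stage or
discharge at 15-minute resolution for months to years either side of an
intervention date, rainfall comes from radar or gauges, and the question is
whether the relationship between event rainfall and event peak flow changed
after the intervention — at the impacted site and not at a control.

`flowatten` implements that analysis chain end to end: series
regularisation, stage–discharge rating, low-flow cleaning, baseflow
separation, storm-event extraction with per-event metrics, and the
statistical layer (rank tests, flashiness indices, Gamma identity-link
GLMs, equal-weight marginal means). A stochastic catchment simulator with a
known attenuation effect makes every stage verifiable without field data.

## From water level to discharge

Gauging structures (typically smooth lined culverts) are rated either
physically or empirically:

* **Manning's equation**: `Q = K A R^0.667 S^0.5 / n`, with flow area `A`
  (m²), hydraulic radius `R = A / P` (`P` the wetted perimeter), bed slope
  `S` and roughness `n` (0.015 for a smooth lined culvert; `K = 1` for
  metric units). Rectangular, circular and trapezoidal sections are
  supported; stage is depth above the section invert, so zero stage means
  zero flow. The exponent is used in its conventional three-decimal form
  0.667 rather than 2/3, so rated discharges reproduce the usual printed
  formula literally. A circular culvert deeper than its diameter is an
  error: pressurised flow is out of scope, not silently extrapolated.
* **Piecewise-spline rating**: discharge regressed on stage with a cubic
  regression spline (`splines::bs` inside `lm`). A rating must be
  invertible, so after fitting the derivative is checked on a dense grid;
  non-monotone fits are refitted with progressively fewer interior knots,
  down to a straight line. The knot count is a configuration parameter
  because gauging campaigns differ; three interior knots is the default.
  Stages outside the gauged range are flagged in the gap mask rather than
  extrapolated.

## Cleaning, and why peaks are sacred

Event detection is sensitive to low-flow sensor noise, so the cleaning rule
classifies each 15-min sample by the local variability of flow: with
centred rolling quantiles, a sample is *elevated* when
`Q75 − Q25` over 12.5 h exceeds the rolling 70th percentile over one month
(`MQ70`). Elevated samples keep their measured value (the variability is
rain-driven); low-flow samples are replaced by a 7.5-h rolling mean.
Numerical choices, all configurable:

* Windows are **centred** (50, 30 and 2880 samples at 15 min). Trailing
  windows would lag the classification and shift apparent event timing;
  centred windows are phase-neutral.
* "One month" is a fixed 30 days so the rule is translation-invariant
  rather than dependent on calendar month boundaries.
* At the record ends the window shrinks (minimum one sample) instead of
  emitting missing values.
* Rolling statistics skip masked samples; masked samples stay masked.
* **Peak preservation**: any measured strict local maximum (±2 samples)
  inside or immediately adjacent to an elevated region retains its measured
  value bit for bit. Event peak metrics additionally always read the
  *measured* series, so cleaning can never alter a reported peak. Note a
  consequence of the rule itself: a storm much shorter than the 12.5-h
  quantile window may never classify as elevated (its samples occupy less
  than a quartile of the window); the final overwrite protects its peak
  regardless.
* Records shorter than the long window (2880 samples) are refused with a
  message stating the minimum length, since `MQ70` would be meaningless.

The implementation keeps a month-long sliding quantile exact and fast with
an order-statistic (Fenwick) tree in C++; tests compare it sample by sample
against a naive quadratic re-computation.

## Baseflow separation

Slow flow (baseflow) and quick flow (stormflow) are split with the
standard recursive digital filter: quickflow
`qf[i] = α qf[i−1] + (1+α)/2 (q[i] − q[i−1])`, clipped to `0 ≤ qf ≤ q` at
every step with the clipped value carried forward, so
`slowflow + quickflow = flow` holds exactly and both components are
non-negative. Defaults follow the standardised sub-daily parameterisation:
`α = 0.925`, three passes in alternating directions, and 30 reflected
samples at each end of the record (discarded after filtering) to suppress
warm-up transients. Gaps split the record: the recursion cannot cross
missing data meaningfully, so each contiguous unmasked segment of at least
60 samples (15 h) is filtered independently and shorter segments stay
masked. The filter is linear in scale — multiplying the flow by a constant
scales both components — which tests assert, alongside a step-by-step
independent recursion.

## Storm-event extraction

Following the usual rules-based pairing of rainfall and flow geometries:

1. **Rainfall periods**: maximal runs of positive rainfall, with internal
   dry spells shorter than 6 h bridged, and periods of less than 1 mm total
   discarded.
2. **Flow responses**: maximal runs where quickflow exceeds
   `max(1.0 × slowflow, 0.001 m³ s⁻¹)` — literally "quick flow exceeds
   slow flow", with a small absolute floor so numerical dust cannot open a
   response. A response runs to the sample where quickflow falls back below
   the criterion (the recession end).
3. **Pairing**: a response belongs to a rainfall period if the two overlap
   or the response starts within 24 h of the rainfall start. Events are the
   connected components of this rain–flow graph: several rainfall periods
   feeding one response merge into one event (total stormflow stays
   well-defined), and one rainfall period followed by several response
   pulses — quickflow can dip transiently below the criterion mid-event —
   spans to the last recession end. Responses never matched to rain are
   kept but flagged as candidate misidentifications; rainfall with no
   response is dropped. When rain falling during a previous event's
   recession pairs with a later response, the later window is clipped at
   the earlier window's end, so surviving windows are always pairwise
   disjoint (a residual overlap raises an error as a sign of
   misconfigured thresholds).

None of the four thresholds (6 h, 1 mm, fraction 1.0 with floor
0.001 m³ s⁻¹, 24 h) is canonical in the literature; they are conservative
defaults and fully exposed in configuration.

Per event, over the half-open window `[start, end)`: total event rainfall
`ER` (mm), total stormflow (`Σ quickflow × 900 s`, m³), peak Q (maximum
*measured* flow, m³ s⁻¹), and the peak-to-peak lag (hours, from the maximum
15-min rainfall depth bin — not a smoothed intensity — to the maximum
flow; ties take the earliest timestamp). Events touching gaps are flagged
and excluded from statistics by default, as are manual exclusions, which
are file-driven (event ids or time ranges) and flag rather than delete.

## Statistical layer

Events are labelled with `beaver` (before/after the site's impact date;
controls inherit their partner's date so both arms share the period
labelling), `season` (wet = `[1 Oct, 1 Apr)`, half-open, so 1 April
00:00 is dry), hydrological year (incrementing each 1 October) and site
role. Summaries report medians and interquartile ranges with two-sided
Mann–Whitney tests (midranks, tie-corrected normal approximation with
continuity correction — records here are far beyond exact-table sizes;
exhaustive enumeration appears only as a test oracle). No multiplicity
correction is applied, and the output metadata says so.

Peak flow is modelled with Gamma GLMs with an **identity** link — event
peaks are positive and right-skewed, and the identity link makes every
coefficient a change in peak flow in m³ s⁻¹ per unit predictor:

* `peak_q ~ rain_mm + beaver` (per site)
* `peak_q ~ rain_mm + beaver * season`
* `peak_q ~ rain_mm + beaver * site` (impact + control pooled)
* `peak_q ~ rain_mm + beaver * season * site`

Treatment contrasts with reference levels before-beaver, dry season,
control site make the `beaver` terms directly interpretable as the
post-impact change. Fitting is IRLS (`stats::glm`) started from an OLS
solution whose fitted means are floored at `1e-6 ×` the median response —
identity-link Gamma likelihoods require strictly positive means, and an
unguarded start can fail outright. Non-convergence or a non-positive
fitted mean at convergence is an error, not a silent result. Dispersion is
the Pearson statistic over residual degrees of freedom. A generic
maximum-likelihood optimiser (the profiled Gamma likelihood depends on the
coefficients only through `Σ log μ + y/μ`) serves as an independent oracle
in the tests.

**Marginal means** are computed on an explicit reference grid: every factor
combination, with total event rainfall fixed at its observed mean (the
natural default; per-cell covariate means would re-introduce exactly the
imbalance the equal-weight averaging is meant to remove). The marginal mean
of a level is the unweighted average of cell predictions over the other
factors' levels; with an identity link the estimate and its standard error
are exact linear forms in the coefficient vector, no delta method. Empty
cells still yield model-based predictions and are flagged. The BACI
contrast `[after − before](impact) − [after − before](control)`, averaged
with equal weight over seasons when present, is the headline attenuation
estimate; its standard error comes from the same linear form.

The high-flow subset keeps events whose peak exceeds the site's Q5 flow
(exceeded 5 % of the time). The threshold is computed from the full
combined record by default so it is period-neutral — computing it from the
pre-period alone would move the threshold with the very effect under test —
with a switch for pre-period-only thresholds. The Q5:Q95 ratio over each
period serves as the flashiness index; a zero Q95 yields a flagged
infinity rather than a number.

## The synthetic catchment

The simulator generates the study conditions the pipeline is validated
under: two sites (impact and control), two 365-day years starting 1
October, the impact date at the midpoint, and a known attenuation effect.

* **Storms**: Poisson arrivals at 0.9 events/day, modulated ±40 % by a
  winter-peaking sinusoid (heaviest storm activity in the wet half-year);
  exponential depths (mean 8 mm), gamma durations (mean 2 h). A fraction
  ρ = 0.8 of storms is shared with the control site (jittered depths);
  each site also draws independent storms at rate `(1 − ρ)` so the
  marginal storm climate matches. Under these conditions each site yields
  roughly 120–150 analysable events per period, comparable to a
  well-instrumented multi-year field campaign.
* **Runoff**: flow = baseflow floor (0.04 m³ s⁻¹) + a slow linear
  reservoir (e-folding 15 days) fed by 30 % of effective rainfall + each
  storm's quickflow: effective rain volume (seasonal runoff coefficient,
  mean 0.25 ± 40 %, winter peak; catchment 1.5 km²) convolved with a
  gamma unit hydrograph (time to peak 3 h, shape 3) normalised to unit
  area.
* **Attenuation acts on the kernel, not on realised flows**: after the
  impact date (wet-season storms only by default) the kernel is replaced
  by one whose discrete peak is `a = 0.6` times the original and whose
  time-to-peak is 1 h later, renormalised to area exactly 1 — attenuation
  redistributes volume, never removes it, which is precisely the
  assumption the BACI design tests. The attenuated kernel's gamma shape is
  solved numerically (monotone bisection bracket + `uniroot`) for the peak
  condition. Because storms have finite duration, realised event-peak
  reductions are somewhat smaller than `1 − a`; the truth tables therefore
  record both the attenuated and the counterfactual unattenuated response
  per storm, and "truth-implied" effects are computed from those realised
  differences, not from the kernel ratio.
* **Noise**: multiplicative lognormal (CV 0.05) applied only where the
  storm response is negligible (quickflow below 5 % of the slow
  component), mirroring real stage sensors whose noise matters at low
  flow, and keeping every storm peak exact ground truth.
* **Determinism**: all randomness derives from one master seed through
  fixed per-component offsets (shared storms, each site's own storms,
  each site's noise), so any sub-stream can be regenerated independently.

What the simulator does **not** emulate: spatially structured rainfall
fields, snow, evapotranspiration, rating-curve drift, autocorrelated
sensor error, or hysteresis in the rainfall–runoff relationship. Passing
tests therefore demonstrate that the pipeline recovers effects under a
well-specified stochastic rainfall–runoff model with Gamma-like event
peaks — not that any particular field record satisfies those assumptions.

## Verification strategy and problem sizes

The test suite checks every numerical core against an independent oracle:
brute-force rolling statistics (10⁴-sample records), a step-by-step filter
recursion, exhaustive Mann–Whitney permutation (n ≤ 8), a generic
maximum-likelihood optimiser (coefficients to 1e-4) and hand linear
algebra for the marginal means (1e-10), plus the `emmeans` package as a
cross-check. Simulation-based checks use the default two-site, two-year
conditions: 100 replicates for recovery of the injected wet-season effect
by the seasonal BACI model (estimate negative and within 2 SE of the
truth-implied value in at least 90 %), and 200 one-site replicates of the
null (`a = 1`) where the additive model's beaver term may reject at the
5 % level in at most 10 % of runs. Conservation is asserted at machine
precision for kernel areas and the flow identity, and at 1 % for event
volumes under attenuation.

## Pipeline orchestration

`validate_config()` reads a YAML run configuration, fills the documented
defaults (one schema, `default_run_config()`), and returns either a
validated object or the complete list of violations — never just the
first. `run_pipeline()` then produces, per site, the prepared series and
diagnostic time-series CSV (event windows overlaid) and the event table;
study-level, the summary table, per-model coefficient and marginal-mean
CSVs, and a JSON manifest hashing inputs, parameters and outputs so a
rerun on identical inputs is verifiably bit-identical. A thin command-line
wrapper (`inst/cli/flowatten.R`) exposes `simulate`, `prepare`, `extract`,
`analyse` and `run` subcommands over these functions.

## Known limitations

* The event-pairing thresholds are declared defaults, not community
  standards; sensitivity to them should be explored per study (the
  `--no-clean` style switches and full parameter exposure exist for that).
* Gamma identity-link GLMs can fail on pathological designs (empty factor
  cells, near-zero peaks); the package errors loudly rather than
  reporting a doubtful fit.
* Filter-derived stormflow volume is itself shaped by the hydrograph:
  flatter, attenuated responses route more of their volume into the
  slow-flow component, so extracted total-stormflow reductions combine
  true attenuation with the filter's geometry. The simulator's truth
  tables keep the two separable (true quick volumes are invariant under
  attenuation even when extracted stormflow is not).
* Events are treated as independent observations; serial correlation
  between nearby storms is not modelled.
* Sub-hourly records only; the window arithmetic assumes a constant
  15-min step after regularisation (other steps work, but defaults are
  tuned for 15 min).
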