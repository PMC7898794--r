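# flowatten

Storm-event extraction and before–after(–control–impact) flow-attenuation
analysis for sub-hourly rainfall and discharge records.

## The problem

Leaky structures in a channel — beaver dam complexes being the motivating
case — can attenuate storm flows: peak discharge falls, the lag from peak
rainfall to peak discharge grows, and the flow regime becomes less flashy,
while the water itself is delayed rather than removed. Attributing such a
change to the intervention requires comparing hundreds of storm events
before and after an impact date, controlling for how much rain each event
delivered, and — where a control catchment exists — checking that the same
contrast is absent there (a BACI design).

`flowatten` is for hydrologists and ecologists running that analysis on
15-minute stage/discharge and rainfall series. It provides the full chain
as tested, pipeable functions returning tibbles:

1. **Rating** — Manning's equation `Q = K A R^0.667 S^0.5 / n` for
   surveyed culvert sections, or monotonicity-enforced piecewise-spline
   rating curves fitted to gaugings (`manning_discharge()`,
   `fit_rating_curve()`, `apply_rating()`).
2. **Preparation** — regularisation onto the 15-min grid with gap masking
   (`regularize()`); a rolling-quantile low-flow cleaning rule — measured
   flow is kept where the 12.5-h interquartile spread exceeds the monthly
   rolling 70th percentile, a 7.5-h rolling mean replaces it elsewhere,
   and event peaks are never altered (`clean_low_flow()`); Lyne–Hollick
   recursive baseflow separation, α = 0.925, 3 passes, reflected ends
   (`separate_baseflow()`).
3. **Events** — continuous-rainfall periods paired with quickflow
   responses (quick flow exceeding slow flow) into disjoint event windows;
   per event: total rainfall ER (mm), total stormflow (m³), peak Q
   (m³ s⁻¹), peak-to-peak lag (h) (`extract_events()`).
4. **Statistics** — factor labelling (beaver period, wet/dry season,
   hydrological year), median/IQR summaries with Mann–Whitney tests,
   Q5:Q95 flashiness indices, Q5-exceedance subsets, Gamma identity-link
   GLMs `peak_q ~ rain_mm + beaver[* season][* site]`, and equal-weight
   estimated marginal means with exact identity-link standard errors
   (`label_events()`, `summarize_events()`, `flashiness_ratio()`,
   `q5_subset()`, `fit_peakflow_glm()`, `marginal_means()`,
   `baci_contrast()`).
5. **Simulation** — a seeded synthetic paired catchment (Poisson-clustered
   winter-peaking storms, gamma unit hydrograph, heteroscedastic low-flow
   noise) with a volume-conserving attenuation effect injected after the
   impact date: kernel peak × a, time-to-peak + Δt, kernel area exactly 1
   (`synthetic_config()`, `generate_study()`).
6. **Orchestration** — YAML-configured end-to-end runs with a hashed
   manifest for bit-reproducibility (`validate_config()`,
   `run_pipeline()`), plus a thin CLI at `inst/cli/flowatten.R`.

## Worked example

Simulate the default two-site, two-year study (attenuation a = 0.6 on
wet-season storms after the midpoint impact date), run the chain, and fit
the seasonal BACI model:

```r
library(flowatten)

cfg <- synthetic_config(seed = 42)
st  <- generate_study(cfg)

run_site <- function(flow, rain, site) {
  base <- separate_baseflow(clean_low_flow(flow))
  base$flow <- flow$value            # peaks always read the measured series
  extract_events(base, rain, site = site)
}

events <- label_events(
  dplyr::bind_rows(
    run_site(st$flow$impact,  st$rain$impact,  "impact"),
    run_site(st$flow$control, st$rain$control, "control")
  ),
  st$design
)

fit <- fit_peakflow_glm(events, "baci_seasonal")
baci_contrast(fit)
#> # A tibble: 1 × 4
#>   estimate      se statistic  p_value
#>      <dbl>   <dbl>     <dbl>    <dbl>
#> 1  -0.0330 0.00912     -3.62 0.000290

marginal_means(fit, margins = c("beaver", "site"))
#> # A tibble: 4 × 5
#>   beaver site    rain_mm emmean      se
#> 1 before control    21.8  0.279 0.00505
#> 2 before impact     21.8  0.278 0.00512
#> 3 after  control    21.8  0.279 0.00498
#> 4 after  impact     21.8  0.245 0.00457
```

Reading the output: the BACI contrast is the change in mean peak flow at
the impact site minus the same change at the control, at equal seasonal
weight and with event rainfall held at its mean — here −0.033 m³ s⁻¹
(p < 0.001), while the control's marginal means are unchanged
(0.279 → 0.279 m³ s⁻¹) and the impact site's fall (0.278 → 0.245). The
simulator's truth tables give the realised injected effect for the same
run (−0.039 m³ s⁻¹), within two standard errors of the estimate. The
flashiness index tells the same story at whole-record level:

```r
flashiness_ratio(st$flow$impact, cfg$impact_date)
#> # A tibble: 2 × 6
#>   period     n    q5    q95 ratio undefined
#> 1 before 35040 0.193 0.0411  4.71 FALSE
#> 2 after  35040 0.185 0.0413  4.47 FALSE
```

`autoplot()` methods exist for fitted models, marginal-mean tables,
baseflow separations and rating curves; `plot_event_extraction()` overlays
event windows on the hydrograph.

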