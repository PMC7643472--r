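# pharmflow

Stock-flow projection of the supply of pharmacists working in community
pharmacies, prescription-based projection of the demand for them, and
evaluation of regional sufficiency — for health-workforce researchers and
planners who need to ask, per region and per year, "will supply meet
demand, and by how much?"

## The model

**Supply** is a deterministic, discrete annual-time-step system-dynamics
model of the pharmacist career path. Each stock obeys
`stock(t+1) = stock(t) + inflow(t) − outflow(t)`, and the pipeline runs:
enrollment *E* → 6-year education → national exam (`takers = final·g·x`,
first-attempt pass rate *q₁*, re-take loop with re-examination rate *r* and
re-take pass rate *q₂*) → graduate school (entry *s*, return-to-pharmacy
*w*) or workplace choice (pharmacy share *c*) → allocation across medical
areas by diffusion shares *d_k* → attrition *a*. The eventual pass fraction
of an exam cohort is the geometric series
`q₁ + (1−q₁)·r·q₂ / (1 − r(1−q₂))` ≈ 0.984 at the base-case rates, and the
test suite holds the simulator to that closed form at 1e-9.

**Demand** is demographic:
`Demand(k, t) = Σᵢ populationᵢ(k, t) · pᵢ / γ`
over 5-year age groups, with *pᵢ* the age-specific prescriptions per person
per year (constant over the horizon) and *γ* = 0.8 the demand coefficient
(the share of pharmacist work time spent on prescriptions).

**Sufficiency** divides supply capacity
(`headcount × 17.64 prescriptions/day × 253.8 days/year`) by demand, both
in prescription-equivalents: ratios below 1 flag shortage, at or above 2
surplus. A relative-RMSE backtest (`sqrt(mean((|ȳ−y|/y)²))`, projected
value in the denominator, threshold 0.1) validates a model against
published head-counts. One-at-a-time sensitivity sweeps and
diffusion-scenario analysis rerun the whole pipeline.

The packaged geography is Hokkaido's 21 secondary medical areas (area
table, population anchors and three diffusion-share scenarios ship as
fixtures). The external inputs the original analysis drew from government
statistics — population projections by age group, prescription rates,
historical head-counts — are emulated by a seeded synthetic generator, so
everything runs end-to-end offline; the packaged baseline bundle is
calibrated to a 2015 prefecture-wide sufficiency ratio of 1.19 and is
synthetic, not a reconstruction.

## Worked example

```r
library(pharmflow)

params <- parameter_set()          # base-case rates
state  <- warm_up_pipeline(params) # steady-state in-education stocks
state
#> <pipeline_state>
#>   students (year 1..n):  399.82, 399.82, 399.82, 399.82, 399.82, 399.82
#>   retakers:              128.16
#>   gradschool (yr 1..n):  5.7, 5.7, 5.7, 5.7
#>   pharmacists:           0 area(s), total 0

areas <- hokkaido_areas()
state$pharmacists <- setNames(as.numeric(areas$pharmacists), areas$area_id)
supply <- simulate_supply(state, params, hokkaido_shares("base"), 2015, 25)
subset(supply, area_id == "TOTAL" & year %in% c(2015, 2025, 2040))
#>   area_id  year value
#> 1 TOTAL    2015 6234
#> 2 TOTAL    2025 7147.
#> 3 TOTAL    2040 8402.

bundle <- gen_baseline_calibrated(synth_config(seed = 1))  # synthetic inputs
demand <- demand_trajectory(bundle$population, bundle$rates, params, 2015:2040)
report <- build_report(supply, demand, params)
subset(report, area_id == "TOTAL" & year %in% c(2015, 2025, 2040))
#>   area_id  year    supply    demand ratio flag
#> 1 TOTAL    2015 27909817. 23453628.  1.19 ok
#> 2 TOTAL    2025 31996992. 22506600.  1.42 ok
#> 3 TOTAL    2040 37613827. 20101131.  1.87 ok
```

Reading: starting from the 6 234 baseline pharmacists, steady licensure
(~304 new licensees/year, 45.8% of whom choose pharmacies) outpaces 0.7%
attrition, so the head-count grows to ~7 147 by 2025 and ~8 402 by 2040
(supply and demand columns are in prescriptions/year). Demand on the
synthetic bundle declines with the shrinking population, so the sufficiency
ratio rises from the calibrated 1.19 to 1.87 — by 2040 several areas cross
the surplus flag (`ratio ≥ 2`):

```r
head(subset(report, year == 2040 & flag != "ok"), 3)[c("area_id", "ratio", "flag")]
#>   area_id       ratio flag
#> 1 Kamikawachubu  2.07 surplus
#> 2 Minamioshima   2.50 surplus
#> 3 Shiribeshi     2.48 surplus
```

`run_sweep()` / `run_scenarios()` rerun this pipeline across sensitivity
ranges and diffusion scenarios, and `run_full()` writes the entire workflow
(inputs, trajectories, sufficiency report, backtest, sweeps, scenarios,
manifest) into a directory of CSV/JSON files; a thin command-line wrapper
lives at `inst/cli/pharmflow.R`. File schemas: `areas.csv`
(`area_id,name,pharmacists,population,aging_rate,land_area_km2`),
`population.csv` (`area_id,year,age_group,persons`), `rates.csv`
(`age_group,prescriptions_per_person_year`), `shares.csv` (`area_id,share`),
`history.csv` (`year,pharmacists`), trajectories
(`area_id,year,value,unit`).

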