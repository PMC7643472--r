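---
title: "Methods: projecting pharmacy pharmacist supply, demand and sufficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting pharmacy pharmacist supply, demand and sufficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmflow)
```

## The problem

Whether a region has enough pharmacists is not a single number: licensure,
workplace choice and attrition move the supply slowly through a long
education pipeline, while demand follows demographic change, which in an
aging, shrinking population first rises and then falls. `pharmflow`
implements a deterministic stock-flow (system-dynamics) projection of the
supply of pharmacists working in community pharmacies, an age-structured
prescription-based demand projection, and their ratio — the sufficiency
ratio — per secondary medical area and prefecture-wide. The packaged
geography is Hokkaido's 21 secondary medical areas.

## Supply: the career-path pipeline

The supply model is the discrete annual realization of
$\mathrm{stock}(t+1) = \mathrm{stock}(t) + \mathrm{inflow}(t) - \mathrm{outflow}(t)$
over the pharmacist career path. Each year, in this order:

1. final-year students graduate and sit the national exam:
   $\mathrm{takers} = \mathrm{final} \cdot g \cdot x$;
2. first-time passes are $\mathrm{takers}\cdot q_1$; failers commit to a
   re-take with probability $r$ and join the re-taker pool, the rest leave
   the system;
3. the pool sits the exam, passing at rate $q_2$; failers re-commit with
   probability $r$;
4. a fraction $s$ of fresh-graduate passers enters graduate school; of the
   remaining passers a fraction $c$ chooses pharmacies;
5. graduate-school finishers contribute a fraction $w$ to pharmacies;
6. the year's new pharmacy pharmacists are split across areas by the
   diffusion shares $d_k$;
7. attrition removes a fraction $a$ of every area stock;
8. cohorts advance one program year and a new enrollment $E$ enters.

The annual time step is deliberate: the exam is annual and every rate is
published per year, so nothing is gained by continuous-time integration.
The within-year order (licensure before employment before attrition) is a
modelling contract, stated here because published descriptions of such
models rarely fix it; all closed-form checks in the test suite assume it.

Two representation choices deserve note:

* **The re-taker pool stores committed re-takers.** The decision to re-sit
  (probability $r$) is applied when a failer *enters* the pool, so the pool
  passes at rate $q_2$ and its failers re-commit at rate $r$. The eventual
  pass fraction of a cohort of takers is then the geometric series
  $q_1 + (1-q_1)\,r\,q_2/(1 - r(1-q_2))$, which at the base-case rates is
  ≈ 0.984 — the pipeline loses very few candidates to the exam itself.
* **Fractional persons are carried unrounded.** Rounding to whole persons
  happens only at report time. Enrollment itself is a fractional average
  (399.824/year) across the observation window.

Negative diffusion shares are legal: trend-derived share vectors show net
outflow for some rural areas. A stock pushed below zero by a negative share
is clamped at 0 and the shortfall logged, not redistributed — this keeps the
published share vectors intact while keeping stocks physical.

Initial conditions are an input, not a constant: the published per-area
head-counts are all-pharmacist 2014 figures, and the pharmacy-only 2015
baseline behind the original projection was never printed, so
`warm_up_pipeline()` supplies steady-state in-education stocks (iterated to
a between-year change below 1e-10, which constant-enrollment recurrences
with rates below 1 always reach) and the caller sets the pharmacist stocks
from whatever baseline table they trust.

## Parameters

| parameter | symbol | unit | default |
|---|---|---|---|
| enrollments | $E$ | persons/year | 399.824 |
| graduation rate | $g$ | fraction | 0.962 |
| examination rate | $x$ | fraction | 0.803 |
| re-examination rate | $r$ | fraction | 0.963 |
| pass rate, first attempt | $q_1$ | fraction | 0.738 |
| pass rate, re-take | $q_2$ | fraction | 0.593 |
| pharmacy choice rate | $c$ | fraction | 0.458 |
| graduate-school entry | $s$ | fraction | 0.025 |
| graduate school to pharmacy | $w$ | fraction | 0.39 |
| attrition rate | $a$ | fraction/year | 0.007 |
| education length | — | years | 6 |
| graduate school length | — | years | 4 |
| prescriptions/pharmacist/day | — | 1/day | 17.64 |
| working days | — | days/year | 253.8 |
| demand coefficient | — | fraction | 0.8 |

Graduate-school entry applies to fresh graduates only (its published
definition is a rate of *new graduates* entering graduate school), so
re-take passers skip it. Graduate school length is nowhere published; 4
years (the standard doctoral course) is the default and it is configurable
— at $s = 0.025$ its effect on the stock is small either way.

## Demand

Demand is demographic:
$$\mathrm{Demand}(k, t) = \sum_i \mathrm{population}_i(k, t)\; p_i \,/\, \gamma,$$
with $i$ over 5-year age groups (18 bins, 0–4 through 85+), $p_i$ the
prescriptions per person per year (held constant over the horizon), and
$\gamma = 0.8$ the demand coefficient — the share of pharmacist work time
spent on prescription-related tasks. Dividing by $\gamma$ converts
prescription volume into total-work demand expressed in
prescription-equivalents. Demand stays in prescription-equivalents
throughout; conversion to head-count terms happens only on the supply side
of the sufficiency ratio. This avoids the ambiguity of "demand in
pharmacists": the two scales differ by the constant capacity per
pharmacist, and keeping each side in its natural unit makes the single
place where $\gamma$ enters auditable (it enters exactly once, on the
demand side — applying it to capacity too would double-count the 80%
share).

One rate table serves every area: area-resolved prescription rates are not
available, a published limitation this package inherits.

## Sufficiency and validation

Supply head-counts convert to capacity as
$\mathrm{capacity} = \mathrm{headcount} \times 17.64 \times 253.8 =
\mathrm{headcount} \times 4477.032$ prescriptions/year. The sufficiency
ratio is capacity/demand: above 1, supply surpasses demand; the report
flags ratios below 1 as shortage and at or above 2 as surplus, the two
thresholds that matter for planning. Zero demand yields a missing ratio,
never infinity.

The backtest uses the relative root-mean-squared error
$$\mathrm{RMSE} = \sqrt{\tfrac{1}{n}\sum_t \left[\,|\bar y_t - y_t|/y_t\,\right]^2},$$
with $y_t$ the *projected* and $\bar y_t$ the published value — note the
projected value in the denominator, which follows the stated convention of
this model family rather than the more common observed-value denominator.
The conventional pass threshold is 0.1.

A literal composition of the published constants cannot reproduce the
published 2015 baseline ratio (dividing total prescriptions by pharmacists
and working days and multiplying back yields the demand coefficient, not
1.19); the pharmacy-only numerators and the separation-rate placement
behind the original arithmetic were not printed. All constants are
therefore independently configurable, and the packaged worked example is
calibrated — and labelled — synthetic.

## Sensitivity and scenarios

`run_sweep()` is strictly one-at-a-time: three levels (lower/base/upper) of
one lever, everything else bit-identical to base. The standard sweep set:
prescriptions per pharmacist per day (15 / 17.6 / 25 — the upper bound
approaches the legal maximum of 40), exam pass rates (±0.10 applied to the
first-time and re-take rates together, as their sensitivity ranges are
published in pairs), enrollments (360 / 399.8 / 440), attrition (0.002 /
0.007 / 0.012), a ±10% multiplier on the prescription-rate table, and
demographic variants supplied as alternative population projections
(realized here as ±0.3%/year compounding on the base population — the model
treats projections as exogenous inputs, so variants are inputs too, not an
internal fertility/mortality model). Report years default to 2025 and 2040.

`run_scenarios()` reruns the pipeline under alternative diffusion-share
vectors. Three ship with the package: the current pharmacist distribution
(base), the 2006–2012 trend, and the 2012–2016/2018 trend (the two period
labels appear inconsistently in the source tables; the fixtures keep the
vectors and both labels without adjudicating). Share vectors are validated
to sum to 1: deviations up to 0.01 are silently renormalized (published
tables are rounded to 0.1%), up to 0.05 renormalized with a warning, and
beyond that rejected.

## The synthetic generator

The population projections, age-specific prescription rates and historical
head-count series behind the original analysis come from government sources
with no machine-readable accession, so `pharmflow` generates them:

* **Population** (`gen_population()`): per-area totals follow the published
  2015/2025/2040 anchors exactly, geometrically interpolated between
  anchors (or a configurable constant decline). The age composition starts
  from a Japan-like reference pyramid, is optionally perturbed by seeded
  multiplicative noise (default relative SD 0.02), and is then rescaled so
  the 65+ share equals the area's published 2015 aging rate plus a drift of
  0.004/year — the pace implied by the published prefecture-wide aging
  trajectory. Totals and the 65+ share are exact by construction; noise
  moves only the within-composition detail.
* **Rates** (`gen_rates()`): a logistic curve in age from 2 to 8
  prescriptions/person/year (inflection 60 y, scale 12 y), flat from 75 up
  (prescription behaviour is assumed not to differ among the over-75
  groups). These levels give a population mean near 4/person/year, the
  order of magnitude implied by dividing plausible prefecture prescription
  volume by population; the calibration step rescales them anyway.
* **History** (`gen_history()`): the simulated head-count series plus
  multiplicative $N(1, \sigma)$ noise (clamped at 0.01) as the "published"
  series, so the backtest can be exercised at known ground truth — with
  many years its RMSE estimates $\sigma$.
* **Calibration** (`gen_baseline_calibrated()`): one scalar on the rate
  table is solved (by root-finding on a bracketing interval, tolerance
  1e-12; the ratio is exactly inversely proportional to the scalar, so the
  root is unique) so the start-year prefecture ratio equals a requested
  target, default 1.19. This makes the synthetic bundle echo the published
  baseline for documentation purposes; it is a synthetic fixture, not a
  reconstruction.

What the generator does **not** emulate: the boom of the over-75 population
inside the 65+ group. With a single 65+ share and realistic drift, demand
under the default bundle declines gently over the whole horizon rather than
rising ~11% to 2025 and falling back as the original projection shows.
Passing tests on synthetic data therefore demonstrate the pipeline's
arithmetic, monotonicity and calibration behaviour — not agreement with the
published demand path, whose inputs are unpublished. The rise-then-fall
regime is exercised separately in the tests with purpose-built aging
populations.

Determinism: every random draw goes through the seeded generator, the
user's RNG state is saved and restored, and a fixed seed gives
byte-identical output files (numbers are printed with 10 significant
digits everywhere).

## Problem sizes

The packaged examples and tests run the full geography (21 areas), the full
horizon (2015–2040, 26 years), 250-year cohort runs for the geometric-series
checks, 50 randomized parameter sets against an independently coded
recurrence oracle, and a 1000-year noise series for the RMSE consistency
check; the complete suite and the end-to-end run each finish in well under
a minute on a laptop.

## Known limitations

No pharmacist migration between areas, no part-time/FTE adjustment, no age
structure of the workforce itself, no morbidity-driven demand, no
geographic accessibility, and no probabilistic sensitivity analysis — the
sweep design is strictly one-at-a-time plus named scenarios. The published
headline endpoints (the 2025/2040 head-counts and sufficiency ratios)
depend on unpublished baselines and are deliberately not hard-coded
anywhere: the simulator projects whatever baseline it is given.
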