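---
title: "Methods: coupled nutrient-balance and farmer-behaviour simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled nutrient-balance and farmer-behaviour simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massai)
```

`massai` simulates the yearly co-evolution of soil nutrient stocks and
farmer management on a smallholder landscape of 10 m plot pixels. This
vignette documents the model, its assumptions, the tunable parameters, the
synthetic-data generator, and the numerical and design choices — in enough
detail that a user can judge what a passing test suite does and does not
establish.

## State, units and the annual tick

The unit of account is the managed soil layer of one plot: pools of N, P,
K and organic C in kg/ha. The layer depth defaults to 0.10 m — the
hand-hoed ridge layer into which fertilizer and manure are placed — and
enters, together with bulk density `rho` (t/m3) and the coarse-fragment
fraction `cf`, only at the concentration/stock boundary:

```{r}
concentration_to_stock(100, rho = 1.3, cf = 0, depth = 0.10)  # mg/kg -> kg/ha
```

Keeping the year-to-year ledger in kg/ha makes the annual update a plain
sum, `X_{t+1} = X_t + sum(IN) - sum(OUT)`, so mass conservation is testable
to floating-point tolerance (the suite asserts 1e-9) rather than modulo
unit conversions. Pools are floored at zero; the unmet outflow is logged
as a positive "clipped deficit" so the ledger identity
`X_{t+1} - X_t - clipped = sum(IN) - sum(OUT)` still closes exactly.

There is no sub-annual time stepping: the tick is one growing calendar
year (the system has uni-modal rainfall, one cropping season per year),
and rainfall enters as an annual total (mm). P and K are tracked as
elements throughout; the oxide grades P2O5/K2O appear only at the
fertilizer-product interface (`P2O5_TO_P = 0.436`, `K2O_TO_K = 0.830`).
Because the inorganic-fertilizer pathway carries N and P only, the shipped
grades (urea, DAP, NPK 23:21:0) are K-free and K-bearing products are
rejected at that interface.

## Environmental flows

The paper family this model belongs to (NUTMON-style nutrient monitoring)
specifies flow pathways and drivers but leaves the transfer functions to
regional calibration. The shipped forms are the standard ones, with every
coefficient in an editable table (`default_eco_coefficients()`; point
estimate plus interval bounds, units documented per row):

- **Atmospheric deposition (IN5):** `a_X * sqrt(rain)`, the classic
  square-root rainfall form; defaults `a_N = 0.14`, `a_P = 0.025`,
  `a_K = 0.05` kg/ha per sqrt(mm) give ~4.2 kg N/ha at 900 mm.
- **Decomposition (IN2):** nutrients released as
  `amount x content x availability` over manure and retained residue; C
  input is the humified fraction (default 0.30) of applied organic C. SOM
  degradation releases `k_soc x SOC` (default 0.02/yr) of C, routed to
  OUT5.
- **Biological N fixation (IN3):** `ndfa x legume biomass x N content`
  (defaults 0.60 and 2.5%).
- **Erosion (OUT3):** multiplicative RUSLE form `R K LS C P` with
  `R = 0.5 x rain`, `K = 0.02`, the fixed-length quadratic
  `LS = 0.065 + 0.0456 s + 0.006541 s^2` (s in %, floor 0.065 at s = 0),
  cover factor 0.30, and `P = 0.5` on plots with conservation structures.
  Nutrient export is the bulk concentration times an enrichment ratio
  (defaults 1.5-2).
- **Sedimentation (IN4):** eroded material is routed one hop along D8
  steepest-descent on the elevation grid (ties broken by lowest neighbour
  index; cells with no strictly lower neighbour export off-grid, which
  makes the routing acyclic by construction — user-supplied routings are
  additionally cycle-checked with a Kahn traversal). A receiving cell
  keeps the sediment delivery ratio (default 0.3); the remainder leaves
  the pixel budget, so landscape deposition can never exceed erosion.
- **Leaching (OUT4):** a fraction
  `clamp(0.25 x rain_m x (1 - clay/60), 0, 1)` — increasing in rainfall,
  decreasing in clay, zero at zero rain — applied to the mineral share of
  the pool (default 2% of total N and K) plus the current year's mineral
  inputs.
- **Gaseous losses (OUT5):** `clamp(0.05 + 0.10 x rain_m, 0, 1)` of the
  current-year mineral N; the C component is the SOM-degradation term
  above.
- **Crop removal (OUT1/OUT2):** grain removes `yield x content`; residue
  biomass is `yield x (1/HI - 1)` (harvest indices 0.45 maize, 0.35
  legume), the non-retained share leaves as OUT2 and the retained share
  feeds next year's decomposition.

The shipped coefficients are order-of-magnitude defaults for a
southern-African maize system — they produce flows of tens of kg/ha/yr —
not calibrated estimates; a site study should load its own table
(`read_eco_coefficients()`). Two timing choices were genuinely open and
are fixed as follows: erosion and its deposition settle within the same
tick (no one-year lag), and residue retained in year t mineralises in
year t+1.

## Farmer decisions

Each practice is a double hurdle: a logit adoption gate and a conditional
intensity model. The gate is realised as a Bernoulli draw rather than a
0.5 threshold, so population adoption rates match the predicted
probabilities in expectation. The intensity link defaults to log (amounts
are positive and right-skewed); predictions are clamped to declared
outcome bounds. Decisions are evaluated in the order legume → fertilizer
→ manure → conservation so that the legume-planted linkage flag exists
when the fertilizer model needs it; conservation structures persist once
built. Yields are bounded GLM predictions with the decided inputs among
the predictors.

Stochasticity between replications comes from the coefficients: each
replication draws one realisation per model from
`Normal(estimate, (ci_hi - ci_lo)/(2 x 1.96))` truncated to the interval.
The truncated normal was chosen over a uniform on the interval (both are
defensible readings of "random within the confidence bounds"); uniform is
available via `coeff_draw: uniform`, and `none` switches to point
estimates. Draws are per replication, not per year, keeping behaviour
coherent within a run while expressing uncertainty between runs. The
shipped behavioural tables use fixed additive half-widths (0.15) for
intercepts and ±25% for slopes: a multiplicative interval on a log-link
intercept would span an implausible outcome range, whereas survey
intercepts are estimated precisely relative to effect sizes.

`fit_double_hurdle()` closes the loop: it estimates a logit on the
adoption indicator and, for the log link, an OLS on log-amounts (the
log-normal intensity model, which is exactly the process the synthetic
generator uses), returning Wald intervals ready to re-enter the simulator
as coefficient tables. Perfect separation in the gate is detected and
rejected, as are datasets below 50 records. `winsorise_drift_adjust()`
implements the baseline-anchoring used when predictions must be
reconciled with observed farm conditions: clipping to baseline
order-statistic quantiles (type-1, so an identical series passes through
unchanged; defaults 1st/99th percentile) followed by rescaling with the
drift coefficient `mean(baseline)/mean(predicted)`.

## Scenarios, population and orchestration

Scenario schedules set the subsidy share per year over the default
20-year horizon. The policy levels are fixed (current 28% — the measured
2016/17 growing-season share — reduced ~15%, zero, universal 70%); the
shapes between those levels were
open and are: constant for current and universal, a linear ramp from 0.28
to 0.02 for reduced (mean exactly 0.15), and removal after year 0 for
zero. All are overridable with an explicit share vector. The progressive
switch advances head age and cultivation period each tick; a hook
registry accepts further update rules (e.g. labour dynamics) without
touching the engine.

The unsampled population is synthesized by within-type resampling of the
surveyed households with a 10%-of-sd normal jitter on continuous
attributes — preserving the empirical joint structure without
distributional assumptions — and plot counts are upscaled by the sampled
land fraction (451 plots at 17.1% → 2637). Synthetic plots are placed by
region growing on free cultivated pixels, with sizes resampled from the
surveyed distribution per farm type; surveyed plots keep their pixels,
and no pixel is assigned twice.

Each (scenario, replication) stream seeds its own RNG via a 32-bit
FNV-1a hash of (master seed, scenario name, replication index), and agents
are iterated in a fixed order within a run. This yields bit-identical
reruns for a given configuration and seed, and stream isolation: one
scenario's results are invariant to which other scenarios are in the
batch. The initial world (population synthesis included) is seeded from
the master seed alone. Every output carries the canonical configuration
hash and the per-run seeds.

## Post-processing

Replicate series are smoothed with a centred moving average (window 3 by
default — the window is a reporting choice, not stated by the model
family — truncated at the series edges so a constant series is a fixed
point), summarised by the mean and empirical 5%/95% quantiles across
replications, and compared between scenarios with Welch two-sample tests
per year under a Bonferroni correction `p_adj = min(1, m p)`. The test
statistic and the family size `m` are configurable; by default `m` counts
the years of one comparison, and the CLI's batch mode multiplies by the
number of scenario pairs. Bonferroni on moving-averaged, hence
autocorrelated, series is conservative; the suite verifies family-wise
error control under the null by direct simulation.

## The synthetic-data generator

`gen_landscape()` builds relief from summed low-frequency harmonics and
soil maps from Gaussian-filtered white noise rescaled to configured
means/sds (defaults: total N 800 mg/kg, P 300 mg/kg, K 1200 mg/kg, SOC
1.5%, clay 25%, bulk density 1.3 t/m3, 60% cultivated). This gives
plausible spatial autocorrelation for exercising the pipeline; it is
explicitly not a digital-soil-mapping method, and the landscape has no
rivers, roads or settlements. `gen_survey()` mirrors the study design it
emulates: 250 households by default, three farm types with an
input-intensity gradient, and a plots-per-household floor-Poisson rate of
1.6 chosen so the expected plot count (~1.80/household, i.e. ~451 plots)
matches the surveyed ratio. `gen_behavioural_truth()` simulates decision
records from the exact two-hurdle process with known coefficients, which
is what makes parameter recovery a testable property.

Passing tests on these fixtures establishes internal correctness —
conservation, determinism, monotonicities, recovery — not predictive
validity for any real landscape: the behavioural and ecological defaults
are plausible magnitudes, not fitted estimates.

## Problem sizes and tolerances

The test suite runs two worlds built at test time: a 60 x 60 landscape
with 25 surveyed households (fast checks) and a 100 x 100 landscape with
50 surveyed households at a 0.3 sampled fraction, run for 2 scenarios x 3
replications x 20 years (the deep conservation, monotonicity and budget
checks). These sizes are the package's chosen desk-scale study
conditions; the generator's full-landscape defaults (400 x 400, 250
households, 17.1% sampled fraction) reproduce the emulated study's
population of ~2637 plots. Mass-balance residuals are asserted below
1e-9; schedule means to 1e-9; parameter recovery over 50 fixed seeds at
n = 2000 with aggregate CI coverage >= 0.90; family-wise error over 500
null repeats within binomial tolerance of 0.05.

## Known limitations

- No endogenous market or price feedback of subsidy on fertilizer prices;
  the subsidy share is an exogenous schedule.
- No process-based crop growth or water balance; yields are regression
  predictions and rainfall is an annual total.
- Sediment routing is single-hop per year; long cascades settle over
  successive years rather than within one.
- Household attributes other than head age (and plot attributes other
  than cultivation period and conservation status) are static unless a
  progressive hook is registered.
- The mineral (leachable) share of total N and K is a fixed configurable
  fraction (default 0.02), a simplification of pool partitioning the
  model family does not resolve.
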