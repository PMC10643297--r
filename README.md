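# massai

Multi-agent simulation of soil nutrient balances on smallholder farming
landscapes under fertilizer-subsidy policy scenarios.

## The problem

In the maize-mixed smallholder systems of East and southern Africa,
continuous cultivation without sufficient nutrient replenishment depletes
soil nitrogen (N), phosphorus (P), potassium (K) and organic carbon (SOC),
and farm input subsidy programmes are the main policy lever on fertilizer
use. Whether a subsidy regime builds or mines soil stocks depends on a
coupled human-environment feedback: farmer decisions (fertilizer, manure,
legumes, residue retention, conservation structures) set the managed
nutrient flows, the environment adds and removes nutrients on its own
(deposition, fixation, erosion and sedimentation, leaching, gaseous
losses), and the resulting stocks feed back into next season's decisions
and yields.

`massai` is for agricultural-systems and policy researchers who want to
simulate those trajectories at the scale of individual 10 m plot pixels
over a multi-year horizon, compare subsidy scenarios with replicated
stochastic runs, and test the whole machinery on fully synthetic data.

## The model

Each plot's managed soil layer (depth D = 0.10 m, bulk density rho,
coarse-fragment fraction cf) carries pools X in {N, P, K, SOC} in kg/ha,
initialised from concentration maps by

    X [kg/ha] = conc [mg/kg] x rho [t/m3] x D [m] x (1 - cf) x 10

and updated once per growing calendar year by the mass balance

    X_{t+1} = X_t + sum(IN1..IN5) - sum(OUT1..OUT5)

over ten pathways: inorganic fertilizer (IN1), decomposition of manure and
retained residues (IN2), biological N fixation (IN3), sediment deposition
(IN4), atmospheric deposition (IN5), grain offtake (OUT1), residue export
(OUT2), erosion (OUT3), leaching (OUT4) and gaseous/SOM-degradation losses
(OUT5). Each pathway carries only its admissible nutrients (e.g. IN1 is
N and P only, OUT4 N and K only); pools are floored at zero with the
clipped deficit logged, so the ledger closes exactly every year.

Farmer decisions follow double-hurdle models: adoption is a Bernoulli gate
at `p = logistic(beta1' x)`, and the conditional intensity is
`g^{-1}(beta2' x)` clamped to outcome bounds (log link by default).
Predictors cover the subsidy share, livelihood profile, natural and social
capital, and cross-practice linkages (legume planting enters the
fertilizer model). Crop yields come from bounded GLM predictors. Every
coefficient carries a confidence interval; each replication draws one
realisation per model (truncated normal within the interval), which is how
the simulation expresses parameter uncertainty. Scenario schedules set the
subsidy share per year: current (0.28 constant), reduced (ramp to 0.02,
mean 0.15), zero (removal after year 0) and universal (0.70).

Replicated runs are summarised by moving averages, empirical 5%/95% bands
across replications, period summaries, and Bonferroni-corrected Welch
tests between scenarios.

## Worked example

A fully synthetic experiment: generate a 60 x 60 landscape with 25
surveyed households, upscale to the full population, and run the two polar
subsidy regimes for 10 years with 2 replications.

```r
library(massai)

dir <- file.path(tempdir(), "demo")
gen_synthetic_inputs(dir, nrows = 60, ncols = 60, n_households = 25, seed = 1,
  config_overrides = list(population = list(sampled_fraction = 0.4),
                          replications = 2, T = 10))
cfg <- load_config(file.path(dir, "config.yaml"))
world <- initialise(cfg)
out <- run_experiment(cfg, scenarios = c("zero", "universal"), world = world)
print(out)
#> <simulation_output> 2 scenario(s) x 2 replication(s) x 10 year(s); 1920 records (config fa2ffe7a)

aggregate(value ~ scenario, mean,
          data = subset(out, variable == "balance_n" & farm_type == "all"))
#>    scenario     value
#> 1 universal -11.97604
#> 2      zero -16.16166

fz <- output_matrix(out, "zero", "fert_kg_ha")
fu <- output_matrix(out, "universal", "fert_kg_ha")
round(c(zero = mean(fz), universal = mean(fu)), 1)
#>      zero universal
#>      40.9      75.0
bonferroni_compare(fz, fu)$significant
#> [1] TRUE
```

Mean fertilizer use responds strongly to the subsidy (40.9 vs 75.0 kg/ha,
Bonferroni-significant), and the population-mean annual N balance is
negative under both regimes (-16.2 vs -12.0 kg N/ha/yr): on this synthetic
landscape the extra fertilizer under universal subsidy offsets only part
of the removals, consistent with nutrient mining under either policy.
Single conversions are available too:

```r
f <- product_to_nutrients(87, "dap")
attr(f, "p2o5")   # 40.02 kg P2O5/ha from the historical basal recommendation
round(f$p, 1)     # 17.4 kg elemental P/ha
```

A thin command-line wrapper ships at `inst/cli/massai.R`
(`synth` / `init` / `run` / `analyze` subcommands). File formats are
documented in `FORMATS.md`; the scientific background and all modelling
choices are in the methods vignette (`vignettes/massai-methods.Rmd`).

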