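# File formats

All files are plain text. Rasters are ESRI ASCII grids; tables are UTF-8 CSV
with a header row. Grids are row-major with the origin at the top-left (row 1
is the northernmost row); cells are 10 m x 10 m = 0.01 ha. Units throughout:
areas in ha, masses in kg (stocks and flows in kg/ha), rainfall in mm, depth
in m, bulk density in t/m3, concentrations in mg/kg fine earth.

## Input directory

An input directory (as written by `gen_synthetic_inputs()` or assembled from
real data) contains:

| file | content |
|---|---|
| `elevation.asc` | elevation, m (slope and D8 flow routing are derived from it) |
| `clay.asc` | clay content, % |
| `bulk_density.asc` | bulk density, t/m3 |
| `n.asc`, `p.asc`, `k.asc`, `soc.asc` | nutrient / organic-C concentration, mg/kg |
| `mask.asc` | cultivated-land mask (1 = cultivated, 0 = not) |
| `plot_map.asc` | surveyed plot membership per pixel (1-based row index into `plots.csv`; NoData = unassigned) |
| `households.csv`, `plots.csv` | survey tables (below) |
| `coefficients.csv`, `models.csv` | behavioural coefficient tables (below); optional, defaults used if absent |
| `eco_coefficients.csv` | ecological parameters (below); optional |
| `config.yaml` | simulation configuration (keys as in `default_config()`) |

## ESRI ASCII grid

Header lines `ncols`, `nrows`, optional `xllcorner`, `yllcorner`, `cellsize`,
`NODATA_value`, followed by `nrows` lines of `ncols` numbers each. Values are
written at `%.10g`, so float data round-trips.

## households.csv

`household_id, farm_type, head_age, head_gender, education, labour, income,
livestock, group_membership, transport_access, communication_access, sampled`

- `farm_type`: 1 (low input), 2 (medium), 3 (high organic + inorganic input)
- `education` in years, `labour` in adult equivalents, `income` in currency
  per year, `livestock` in tropical livestock units (TLU)
- `group_membership`, `transport_access`, `communication_access`, `sampled`:
  logical (TRUE/FALSE)

## plots.csv

`plot_id, household_id, row, col, npix, area_ha, slope, clay, tpi,
cultivation_period, swc_flag, maize_frac, legume_frac, fallow_frac,
residue_retained_fraction`

- `row`, `col`: 1-based anchor pixel of the plot; `npix` pixel count;
  `area_ha = npix x 0.01`
- `slope` in %, `clay` in %, `tpi` topographic position (ordinal 1-3),
  `cultivation_period` in years
- crop fractions in [0, 1] summing to <= 1; `residue_retained_fraction` in
  [0, 1]
- every `household_id` must exist in `households.csv` (readers reject
  orphans)

## coefficients.csv + models.csv

`coefficients.csv`: `model, predictor, estimate, ci_lo, ci_hi` with
`ci_lo <= estimate <= ci_hi`. `models.csv`: `model, link, bound_min,
bound_max` declaring the outcome link (`logit`, `log`, `identity`) and clamp
bounds per model. Models: `adopt_fert`, `qty_fert`, `adopt_manure`,
`qty_manure`, `adopt_legume`, `share_legume`, `adopt_swc`, `yield_maize`,
`yield_legume`. Predictor names must match the decision-context columns
(see `build_context()`), with `intercept` for the constant term.

## eco_coefficients.csv

`name, estimate, lo, hi, units` with `lo <= estimate <= hi`; parameter names
as in `default_eco_coefficients()`. A documented default file ships at
`inst/extdata/eco_coefficients.csv`.

## Simulation output

`run_experiment()` returns (and `write_output()` saves as `results.csv`)
long-format records `scenario, replication, year, farm_type, variable,
value`, where `farm_type` is `all`, `1`, `2` or `3` and `variable` is one of
`fert_kg_ha, manure_kg_ha, maize_yield, legume_yield, balance_n, balance_p,
balance_k, balance_c, stock_n, stock_p, stock_k, stock_c` (means over
plots). `provenance.txt` records the config hash and the per-run seeds.
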