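# Environment-driven nutrient flows: atmospheric deposition, decomposition,
# biological N fixation, erosion + sediment routing, leaching and gaseous
# losses, and yield-driven crop removal. Functional forms follow the NUTMON
# family of transfer functions (deposition proportional to sqrt(rainfall),
# leaching and gaseous losses as bounded fractions, multiplicative
# RUSLE-style erosion); every coefficient lives in an editable table with a
# point estimate and interval bounds, so calibrated values can be loaded for
# a real study area.

#' Default ecological coefficient table
#'
#' Point estimates with interval bounds (`lo`, `hi`) for every parameter of
#' the ecological sub-models. The shipped values are order-of-magnitude
#' defaults for a southern-African maize system producing flows of tens of
#' kg/ha/yr; site studies should load calibrated values via
#' [read_eco_coefficients()].
#'
#' @return data.frame with columns `name`, `estimate`, `lo`, `hi`, `units`.
#' @export
default_eco_coefficients <- function() {
  row <- function(name, est, units, spread = 0.2) {
    data.frame(name = name, estimate = est, lo = est * (1 - spread),
               hi = est * (1 + spread), units = units, stringsAsFactors = FALSE)
  }
  rbind(
    row("dep_a_n", 0.14, "kg/ha per sqrt(mm)"),
    row("dep_a_p", 0.025, "kg/ha per sqrt(mm)"),
    row("dep_a_k", 0.05, "kg/ha per sqrt(mm)"),
    row("manure_n", 0.012, "fraction"), row("manure_p", 0.003, "fraction"),
    row("manure_k", 0.010, "fraction"), row("manure_c", 0.30, "fraction"),
    row("residue_n", 0.007, "fraction"), row("residue_p", 0.001, "fraction"),
    row("residue_k", 0.012, "fraction"), row("residue_c", 0.40, "fraction"),
    row("avail_n", 0.50, "fraction"), row("avail_p", 0.60, "fraction"),
    row("avail_k", 0.80, "fraction"),
    row("humification", 0.30, "fraction"),
    row("k_soc", 0.020, "1/yr"),
    row("ndfa", 0.60, "fraction"),
    row("legume_n", 0.025, "fraction"),
    row("rusle_r_per_mm", 0.50, "MJ mm/(ha h yr) per mm rain"),
    row("rusle_k", 0.020, "t ha h/(ha MJ mm)"),
    row("rusle_c_cover", 0.30, "unitless"),
    row("p_swc", 0.50, "unitless"),
    row("er_n", 2.0, "unitless"), row("er_p", 2.0, "unitless"),
    row("er_k", 1.5, "unitless"), row("er_c", 2.0, "unitless"),
    row("sdr", 0.30, "fraction"),
    row("leach_rate", 0.25, "fraction per m rain"),
    row("leach_clay_max", 60, "%"),
    row("mineral_n_frac", 0.02, "fraction"),
    row("mineral_k_frac", 0.02, "fraction"),
    row("gas_base", 0.05, "fraction"),
    row("gas_rain", 0.10, "fraction per m rain"),
    row("hi_maize", 0.45, "fraction"), row("hi_legume", 0.35, "fraction"),
    row("grain_n_maize", 0.016, "fraction"), row("grain_p_maize", 0.003, "fraction"),
    row("grain_k_maize", 0.004, "fraction"),
    row("grain_n_legume", 0.035, "fraction"), row("grain_p_legume", 0.004, "fraction"),
    row("grain_k_legume", 0.010, "fraction")
  )
}

#' Collapse an ecological coefficient table to named point values
#'
#' @param coeffs a coefficient data.frame (`name`, `estimate`, `lo`, `hi`) as
#'   from [default_eco_coefficients()] or [read_eco_coefficients()], or an
#'   already-named numeric vector (returned unchanged).
#' @param draws optional named numeric vector of realised values (e.g. from
#'   [draw_eco_coefficients()]) overriding the point estimates.
#' @return named numeric vector of parameter values.
#' @export
as_eco_params <- function(coeffs, draws = NULL) {
  if (is.numeric(coeffs) && !is.null(names(coeffs))) return(coeffs)
  stopifnot(is.data.frame(coeffs))
  if (any(coeffs$lo > coeffs$estimate | coeffs$estimate > coeffs$hi))
    stop("eco coefficients must satisfy lo <= estimate <= hi")
  ec <- stats::setNames(coeffs$estimate, coeffs$name)
  if (!is.null(draws)) ec[names(draws)] <- draws
  ec
}

#' Draw one realisation of the ecological coefficients
#'
#' Each parameter is drawn from a normal centred on its estimate with
#' sd `(hi - lo) / (2 * 1.96)`, truncated to `[lo, hi]` (`method =
#' "uniform"` draws uniformly on the interval instead). Intended to be drawn
#' once per replication.
#'
#' @param coeffs coefficient data.frame (`name`, `estimate`, `lo`, `hi`).
#' @param method `"truncnorm"` (default) or `"uniform"`.
#' @return named numeric vector.
#' @export
draw_eco_coefficients <- function(coeffs, method = c("truncnorm", "uniform")) {
  method <- match.arg(method)
  vals <- if (method == "uniform") {
    ifelse(coeffs$hi > coeffs$lo, stats::runif(nrow(coeffs), coeffs$lo, coeffs$hi),
           coeffs$estimate)
  } else {
    mapply(function(e, l, h) rtruncnorm(1, e, (h - l) / (2 * 1.96), l, h),
           coeffs$estimate, coeffs$lo, coeffs$hi)
  }
  stats::setNames(vals, coeffs$name)
}

#' Wet and dry atmospheric deposition (IN5)
#'
#' `X = a_X * sqrt(rain)` for N, P, K — deposition scales with the square
#' root of annual rainfall.
#'
#' @param rain_mm annual rainfall, mm; non-negative scalar.
#' @param ec named eco parameter vector (see [as_eco_params()]).
#' @return [flow_vector] with pathway `IN5`.
#' @export
atmospheric_deposition <- function(rain_mm, ec) {
  if (any(rain_mm < 0)) stop("rain_mm must be >= 0")
  flow_vector("IN5",
              n = ec[["dep_a_n"]] * sqrt(rain_mm),
              p = ec[["dep_a_p"]] * sqrt(rain_mm),
              k = ec[["dep_a_k"]] * sqrt(rain_mm))
}

#' Decomposition of manure, retained residues and soil organic matter (IN2)
#'
#' Nutrients released are `amount x content x availability` summed over
#' manure and retained residue; the C input is the humified fraction of the
#' organic C applied. SOM degradation releases `k_soc x SOC` of C, which the
#' caller routes to the gaseous/degradation output pathway (OUT5).
#'
#' @param manure_kg_ha manure applied, kg/ha (vector per plot).
#' @param residue_kg_ha residue biomass retained from the previous season,
#'   kg/ha.
#' @param stock a [soil_stock] (for the SOC pool).
#' @param ec named eco parameter vector.
#' @return list: `flow` ([flow_vector] `IN2`), `soc_loss_c` (kg C/ha from SOM
#'   degradation).
#' @export
mineralisation <- function(manure_kg_ha, residue_kg_ha, stock, ec) {
  if (any(manure_kg_ha < 0) || any(residue_kg_ha < 0)) stop("amounts must be >= 0")
  rel <- function(nut) {
    (manure_kg_ha * ec[[paste0("manure_", nut)]] +
       residue_kg_ha * ec[[paste0("residue_", nut)]]) * ec[[paste0("avail_", nut)]]
  }
  c_in <- ec[["humification"]] * (manure_kg_ha * ec[["manure_c"]] +
                                    residue_kg_ha * ec[["residue_c"]])
  list(flow = flow_vector("IN2", n = rel("n"), p = rel("p"), k = rel("k"), c = c_in),
       soc_loss_c = ec[["k_soc"]] * stock$soc)
}

#' Biological nitrogen fixation by legumes (IN3)
#'
#' `N = ndfa * biomass * legume N content`, where `ndfa` is the fraction of
#' legume N derived from the atmosphere.
#'
#' @param legume_biomass_kg_ha above-ground legume biomass, kg/ha.
#' @param ec named eco parameter vector.
#' @return [flow_vector] with pathway `IN3`.
#' @export
biological_n_fixation <- function(legume_biomass_kg_ha, ec) {
  if (any(legume_biomass_kg_ha < 0)) stop("biomass must be >= 0")
  flow_vector("IN3", n = ec[["ndfa"]] * legume_biomass_kg_ha * ec[["legume_n"]])
}

# Fixed-length RUSLE LS approximation, quadratic in slope percent.
ls_factor <- function(slope_pct) 0.065 + 0.0456 * slope_pct + 0.006541 * slope_pct^2

#' Annual soil loss by erosion (multiplicative RUSLE form)
#'
#' `loss = R * K * LS(slope) * C_cover * P`, t/ha/yr, with the support
#' practice factor `P < 1` on plots with soil and water conservation
#' structures. Non-decreasing in slope.
#'
#' @param plot data.frame with at least `slope` (%) and `swc_flag` (logical);
#'   vectorised over rows.
#' @param ec named eco parameter vector.
#' @param rain_mm annual rainfall, mm (drives the erosivity factor R).
#' @return soil loss, t/ha/yr (vector).
#' @export
soil_erosion <- function(plot, ec, rain_mm) {
  if (any(plot$slope < 0)) stop("slope must be >= 0")
  r_fac <- ec[["rusle_r_per_mm"]] * rain_mm
  p_fac <- ifelse(plot$swc_flag, ec[["p_swc"]], 1)
  r_fac * ec[["rusle_k"]] * ls_factor(plot$slope) * ec[["rusle_c_cover"]] * p_fac
}

#' Nutrient export with eroded soil (OUT3)
#'
#' Each nutrient leaves at the sediment's concentration, i.e. the bulk-soil
#' concentration (via [stock_to_concentration()]) times an enrichment ratio.
#'
#' @param soil_loss_t_ha soil loss, t/ha/yr.
#' @param stock a [soil_stock].
#' @param ec named eco parameter vector.
#' @return [flow_vector] with pathway `OUT3`.
#' @export
erosion_nutrient_loss <- function(soil_loss_t_ha, stock, ec) {
  conc <- function(pool) stock_to_concentration(stock[[pool]], stock$rho,
                                                stock$cf, stock$depth)
  # t/ha * mg/kg * 1e-3 = kg/ha
  amt <- function(pool, er) soil_loss_t_ha * conc(pool) * ec[[er]] * 1e-3
  flow_vector("OUT3", n = amt("n", "er_n"), p = amt("p", "er_p"),
              k = amt("k", "er_k"), c = amt("soc", "er_c"))
}

#' Steepest-descent (D8) flow routing on an elevation grid
#'
#' Each cell drains to its strictly lower steepest neighbour (8-neighbour,
#' distance-weighted drop); ties broken by lowest neighbour index; cells with
#' no lower neighbour (pits, flats, edges draining outward) export off-grid.
#' Routing to strictly lower cells only makes the graph acyclic by
#' construction.
#'
#' @param elevation numeric matrix.
#' @return integer vector of length `nrow*ncol` (column-major cell index of
#'   the receiving cell, `NA` = exports off the landscape).
#' @export
flow_routing <- function(elevation) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  best_drop <- matrix(0, nr, nc)
  best_idx <- matrix(NA_integer_, nr, nc)
  for (j in seq_len(nrow(offsets))) {
    dr <- offsets$dr[j]; dc <- offsets$dc[j]
    dist <- sqrt(dr^2 + dc^2)
    if (max(1, 1 - dr) > min(nr, nr - dr) ||
        max(1, 1 - dc) > min(nc, nc - dc)) next
    rs <- seq(max(1, 1 - dr), min(nr, nr - dr))
    cs <- seq(max(1, 1 - dc), min(nc, nc - dc))
    nb <- matrix(NA_real_, nr, nc)
    nb[rs, cs] <- elevation[rs + dr, cs + dc]
    drop <- (elevation - nb) / dist
    idx <- matrix(NA_integer_, nr, nc)
    idx[rs, cs] <- outer(rs + dr, (cs + dc - 1L) * nr, `+`)
    cand <- !is.na(drop) & drop > 0 &
      (drop > best_drop |
         (drop == best_drop & (is.na(best_idx) | idx < best_idx)))
    best_drop[cand] <- drop[cand]
    best_idx[cand] <- idx[cand]
  }
  as.vector(best_idx)
}

# Kahn-style cycle check on a functional graph (each node has <= 1 out-edge).
assert_acyclic_routing <- function(routing) {
  n <- length(routing)
  indeg <- tabulate(routing[!is.na(routing)], nbins = n)
  queue <- which(indeg == 0)
  seen <- 0L
  removed <- logical(n)
  while (length(queue)) {
    v <- queue[[length(queue)]]
    queue <- queue[-length(queue)]
    removed[v] <- TRUE
    seen <- seen + 1L
    t <- routing[[v]]
    if (!is.na(t) && !removed[t]) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) queue <- c(queue, t)
    }
  }
  if (seen < n) stop("cyclic flow routing: routing graph must be acyclic")
  invisible(TRUE)
}

#' Sediment and nutrient deposition from upslope erosion (IN4)
#'
#' Routes each cell's eroded soil (and its nutrient load) to its downslope
#' receiver; a receiving cell keeps the sediment delivery ratio `sdr` of what
#' arrives. Single-hop delivery: material not deposited leaves the pixel
#' budget (streams/export), so landscape-wide deposition never exceeds
#' erosion.
#'
#' @param soil_loss vector of eroded soil per cell, t/ha (cell order
#'   column-major, matching `routing`).
#' @param nutrient_loss list of per-cell eroded nutrient vectors (`n`, `p`,
#'   `k`, `c`), kg/ha, as from [erosion_nutrient_loss()].
#' @param routing receiver index per cell (from [flow_routing()]); validated
#'   acyclic.
#' @param ec named eco parameter vector (uses `sdr`).
#' @return list: `soil` (t/ha deposited per cell) and `flow` ([flow_vector]
#'   `IN4` per cell).
#' @export
sediment_deposition <- function(soil_loss, nutrient_loss, routing, ec) {
  assert_acyclic_routing(routing)
  n <- length(routing)
  stopifnot(length(soil_loss) == n)
  d <- ec[["sdr"]]
  acc <- function(x) {
    out <- numeric(n)
    ok <- which(!is.na(routing))
    if (length(ok)) {
      agg <- tapply(x[ok], routing[ok], sum)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
    d * out
  }
  list(soil = acc(soil_loss),
       flow = flow_vector("IN4", n = acc(nutrient_loss$n), p = acc(nutrient_loss$p),
                          k = acc(nutrient_loss$k), c = acc(nutrient_loss$c)))
}

#' Leaching losses of N and K (OUT4)
#'
#' A leachable fraction `f = clamp(leach_rate * rain_m * (1 - clay/clay_max),
#' 0, 1)` — increasing in rainfall, decreasing in clay — is applied to the
#' mineral share of the soil pool plus the current year's mineral inputs.
#'
#' @param rain_mm annual rainfall, mm.
#' @param clay_pct clay content, % (vector per plot).
#' @param stock a [soil_stock].
#' @param mineral_n_inputs current-year mineral N inputs (fertilizer N +
#'   mineralised N), kg/ha.
#' @param ec named eco parameter vector.
#' @param mineral_k_inputs current-year soluble K inputs, kg/ha (default 0).
#' @return [flow_vector] with pathway `OUT4`.
#' @export
leaching_loss <- function(rain_mm, clay_pct, stock, mineral_n_inputs, ec,
                          mineral_k_inputs = 0) {
  if (any(rain_mm < 0)) stop("rain_mm must be >= 0")
  f <- clamp(ec[["leach_rate"]] * (rain_mm / 1000) *
               pmax(0, 1 - clay_pct / ec[["leach_clay_max"]]), 0, 1)
  flow_vector("OUT4",
              n = f * (ec[["mineral_n_frac"]] * stock$n + mineral_n_inputs),
              k = f * (ec[["mineral_k_frac"]] * stock$k + mineral_k_inputs))
}

#' Gaseous N losses by denitrification and volatilisation (OUT5, N part)
#'
#' A bounded fraction `clamp(gas_base + gas_rain * rain_m, 0, 1)` of the
#' current-year mineral N (fertilizer + mineralised). The C component of
#' OUT5 (soil-organic-matter degradation) is produced by [mineralisation()]
#' and added by the caller.
#'
#' @param fert_n fertilizer N applied, kg/ha.
#' @param rain_mm annual rainfall, mm.
#' @param mineralised_n mineralised N this year, kg/ha.
#' @param ec named eco parameter vector.
#' @param soc_loss_c SOM degradation C to carry on this pathway, kg/ha.
#' @return [flow_vector] with pathway `OUT5`.
#' @export
gaseous_loss <- function(fert_n, rain_mm, mineralised_n, ec, soc_loss_c = 0) {
  if (any(rain_mm < 0)) stop("rain_mm must be >= 0")
  g <- clamp(ec[["gas_base"]] + ec[["gas_rain"]] * (rain_mm / 1000), 0, 1)
  flow_vector("OUT5", n = g * (fert_n + mineralised_n), c = soc_loss_c)
}

#' Nutrient removal in harvested grain and exported residues (OUT1, OUT2)
#'
#' Grain removes `yield x grain content`. Residue biomass is
#' `yield * (1/HI - 1)` (harvest index HI); the non-retained share leaves as
#' OUT2, and the retained biomass is returned for next season's
#' mineralisation.
#'
#' @param maize_yield_kg_ha,legume_yield_kg_ha plot-level yields, kg/ha
#'   (already scaled by crop area shares).
#' @param residue_retained_fraction fraction of residue biomass kept on the
#'   plot, in `[0, 1]`.
#' @param ec named eco parameter vector.
#' @return list: `out1`, `out2` ([flow_vector]s) and `residue_retained_kg_ha`
#'   (biomass passed to next year's mineralisation).
#' @export
crop_removal <- function(maize_yield_kg_ha, legume_yield_kg_ha,
                         residue_retained_fraction, ec) {
  if (any(residue_retained_fraction < 0 | residue_retained_fraction > 1))
    stop("residue_retained_fraction must be in [0, 1]")
  g <- function(nut) {
    maize_yield_kg_ha * ec[[paste0("grain_", nut, "_maize")]] +
      legume_yield_kg_ha * ec[[paste0("grain_", nut, "_legume")]]
  }
  res_biomass <- maize_yield_kg_ha * (1 / ec[["hi_maize"]] - 1) +
    legume_yield_kg_ha * (1 / ec[["hi_legume"]] - 1)
  removed <- 1 - residue_retained_fraction
  r <- function(nut) res_biomass * ec[[paste0("residue_", nut)]] * removed
  list(out1 = flow_vector("OUT1", n = g("n"), p = g("p"), k = g("k")),
       out2 = flow_vector("OUT2", n = r("n"), p = r("p"), k = r("k")),
       residue_retained_kg_ha = res_biomass * residue_retained_fraction)
}
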