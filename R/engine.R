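# Orchestration: initialise -> simulate -> output. One tick is a growing
# calendar year; phases within a tick are fixed: (1) progressive update,
# (2) behavioural decisions, (3) environment-driven flows, (4) yield
# prediction, (5) crop removal, (6) stock update, (7) recording.

#' Initialise a simulation world from an input directory
#'
#' Loads the landscape rasters and survey tables, derives slope and flow
#' routing from elevation, initialises per-plot soil stocks from the
#' concentration maps via [concentration_to_stock()], and synthesizes the
#' unsampled household population (unless disabled). The initial RNG state
#' is derived from the master seed alone, so the same configuration always
#' produces the same world regardless of which scenarios are later run.
#'
#' @param config configuration from [load_config()] with `input_dir` set.
#' @return a `world` list: `households`, `plots` (with `stock_*`, `rho`,
#'   `residue_prev` columns), `grid` (rasters, `plot_map`, `routing`),
#'   `tables`, `eco`, `config`.
#' @export
initialise <- function(config) {
  dir <- config$input_dir
  if (is.null(dir)) stop("config$input_dir is not set")
  rast <- function(name) {
    path <- file.path(dir, paste0(name, ".asc"))
    if (!file.exists(path)) stop("missing raster: ", path)
    read_raster(path)$data
  }
  elevation <- rast("elevation")
  clay <- rast("clay")
  bd <- rast("bulk_density")
  conc <- list(n = rast("n"), p = rast("p"), k = rast("k"), soc = rast("soc"))
  mask <- rast("mask") > 0
  plot_map <- rast("plot_map")
  plot_map[is.na(plot_map)] <- NA_integer_
  slope <- slope_from_elevation(elevation)

  survey <- read_survey(dir)
  households <- survey$households
  plots <- survey$plots

  coef_path <- file.path(dir, "coefficients.csv")
  tables <- if (file.exists(coef_path)) read_coefficients(coef_path)
            else default_coefficient_tables()
  eco_path <- file.path(dir, "eco_coefficients.csv")
  eco <- if (file.exists(eco_path)) read_eco_coefficients(eco_path)
         else default_eco_coefficients()

  set.seed(stream_seed(config$master_seed, "init", 0))
  if (isTRUE(config$population$synthesize)) {
    target_hh <- round(nrow(households) / config$population$sampled_fraction)
    households <- synthesize_households(
      households, target_hh,
      jitter_sd_frac = config$population$jitter_sd_frac)
    placed <- assign_plots(households, plots, mask,
                           plot_map = matrix(as.integer(plot_map),
                                             nrow(mask), ncol(mask)))
    plots <- placed$plots
    plot_map <- placed$plot_map
  }

  # per-plot terrain and soil state from the rasters
  pm_vec <- as.vector(plot_map)
  cells_of <- split(seq_along(pm_vec), pm_vec)
  plot_mean <- function(m) {
    v <- as.vector(m)
    out <- vapply(cells_of, function(ix) mean(v[ix], na.rm = TRUE), numeric(1))
    out[match(seq_len(nrow(plots)), as.integer(names(cells_of)))]
  }
  plots$slope <- plot_mean(slope)
  plots$clay <- plot_mean(clay)
  plots$rho <- plot_mean(bd)
  for (nut in names(conc)) {
    plots[[paste0("stock_", nut)]] <- concentration_to_stock(
      plot_mean(conc[[nut]]), plots$rho, config$coarse_fragments,
      config$depth_m)
  }
  plots$residue_prev <- 0
  fts <- households$farm_type[match(plots$household_id,
                                    households$household_id)]
  plots$farm_type <- fts

  list(
    households = households,
    plots = plots,
    grid = list(elevation = elevation, slope = slope, clay = clay,
                mask = mask, plot_map = plot_map,
                routing = flow_routing(elevation),
                nrows = nrow(elevation), ncols = ncol(elevation)),
    tables = tables,
    eco = eco,
    config = config
  )
}

# Pixel-level erosion routing: spread each plot's per-ha soil loss onto its
# pixels, route downslope, and average the deposition back per plot.
route_erosion <- function(world, soil_loss, out3) {
  pm <- as.vector(world$grid$plot_map)
  n_cells <- length(pm)
  px_loss <- numeric(n_cells)
  in_plot <- !is.na(pm)
  px_loss[in_plot] <- soil_loss[pm[in_plot]]
  px_nut <- lapply(c(n = "n", p = "p", k = "k", c = "c"), function(nut) {
    v <- numeric(n_cells)
    v[in_plot] <- out3[[nut]][pm[in_plot]]
    v
  })
  dep <- sediment_deposition(px_loss, px_nut, world$grid$routing,
                             c(sdr = world$ec[["sdr"]]))
  back <- function(v) {
    agg <- tapply(v[in_plot], pm[in_plot], mean)
    out <- numeric(length(soil_loss))
    out[as.integer(names(agg))] <- as.numeric(agg)
    out
  }
  list(flow = flow_vector("IN4", n = back(dep$flow$n), p = back(dep$flow$p),
                          k = back(dep$flow$k), c = back(dep$flow$c)),
       soil = back(dep$soil),
       landscape_eroded = sum(px_loss), landscape_deposited = sum(dep$soil))
}

#' Advance the world by one growing calendar year
#'
#' Runs the fixed phase order (progressive update, decisions, ecological
#' flows, yields, crop removal, stock update, recording) and returns the
#' updated world together with the year's plot-level ledger.
#'
#' @param world world list from [initialise()] (with realised coefficients
#'   attached by [run_experiment()], or pass `draws`/`ec` here).
#' @param year simulation year (0-based tick index).
#' @param s_t subsidy share for the year.
#' @param draws named list of realised behavioural coefficient vectors
#'   (`NULL` = point estimates).
#' @param ec named realised ecological parameter vector (`NULL` = point
#'   estimates).
#' @return list: `world` (advanced), `ledger` (per-plot data.frame with
#'   decisions, yields, per-nutrient inflow/outflow sums, clipped deficits
#'   and closing stocks), `sediment` (landscape eroded/deposited t).
#' @export
step_year <- function(world, year, s_t, draws = NULL, ec = NULL) {
  cfg <- world$config
  if (is.null(ec)) ec <- as_eco_params(world$eco)
  world$ec <- ec
  rain <- cfg$rain_mm

  # (1) progressive variables
  world <- progressive_update(world, progressive = isTRUE(cfg$progressive))
  plots <- world$plots
  households <- world$households

  # (2) farmer decisions
  dec <- decide_all(households, plots, s_t, world$tables, draws)
  maize_frac <- pmax(0, 1 - plots$fallow_frac - dec$legume_fraction)

  stock <- soil_stock(plots$stock_n, plots$stock_p, plots$stock_k,
                      plots$stock_soc, rho = plots$rho,
                      cf = cfg$coarse_fragments, depth = cfg$depth_m)

  # (3) environment-driven flows
  in1 <- product_to_nutrients(dec$fert_kg_ha, cfg$fert_product)
  in5 <- atmospheric_deposition(rain, ec)
  min_out <- mineralisation(dec$manure_kg_ha, plots$residue_prev, stock, ec)
  in2 <- min_out$flow
  plots$swc_flag <- dec$swc_flag
  soil_loss <- soil_erosion(plots, ec, rain)
  out3 <- erosion_nutrient_loss(soil_loss, stock, ec)
  routed <- route_erosion(world, soil_loss, out3)
  in4 <- routed$flow
  out4 <- leaching_loss(rain, plots$clay, stock,
                        mineral_n_inputs = in1$n + in2$n, ec,
                        mineral_k_inputs = in2$k)
  out5 <- gaseous_loss(in1$n, rain, in2$n, ec,
                       soc_loss_c = min_out$soc_loss_c)

  # (4) yields (per cropped ha), with decided inputs as predictors
  ctx <- build_context(households, plots, s_t,
                       extra = list(legume_planted = as.numeric(dec$legume_fraction > 0),
                                    fert_kg_100 = dec$fert_kg_ha / 100,
                                    manure_t = dec$manure_kg_ha / 1000))
  maize_yield <- predict_yield(ctx, world$tables$yield_maize,
                               draws$yield_maize)
  legume_yield <- predict_yield(ctx, world$tables$yield_legume,
                                draws$yield_legume)
  maize_plot <- maize_yield * maize_frac
  legume_plot <- legume_yield * dec$legume_fraction

  # (5) crop removal and N fixation from the realised legume biomass
  removal <- crop_removal(maize_plot, legume_plot,
                          dec$residue_retained_fraction, ec)
  legume_biomass <- if (ec[["hi_legume"]] > 0) legume_plot / ec[["hi_legume"]]
                    else 0 * legume_plot
  in3 <- biological_n_fixation(legume_biomass, ec)

  # (6) mass-balance stock update
  inflows <- list(in1, in2, in3, in4, in5)
  outflows <- list(removal$out1, removal$out2, out3, out4, out5)
  upd <- update_soil_stock(stock, inflows, outflows)
  plots$stock_n <- upd$stock$n
  plots$stock_p <- upd$stock$p
  plots$stock_k <- upd$stock$k
  plots$stock_soc <- upd$stock$soc
  plots$residue_prev <- removal$residue_retained_kg_ha
  plots$legume_frac <- dec$legume_fraction
  plots$maize_frac <- maize_frac

  sum_flows <- function(flows, nut) {
    tot <- 0
    for (f in flows) tot <- tot + f[[nut]]
    tot
  }
  ledger <- data.frame(
    plot_id = plots$plot_id, farm_type = plots$farm_type, year = year,
    fert_kg_ha = dec$fert_kg_ha, manure_kg_ha = dec$manure_kg_ha,
    legume_fraction = dec$legume_fraction,
    maize_yield = maize_yield, legume_yield = legume_yield,
    in_n = sum_flows(inflows, "n"), in_p = sum_flows(inflows, "p"),
    in_k = sum_flows(inflows, "k"), in_c = sum_flows(inflows, "c"),
    out_n = sum_flows(outflows, "n"), out_p = sum_flows(outflows, "p"),
    out_k = sum_flows(outflows, "k"), out_c = sum_flows(outflows, "c"),
    clip_n = upd$clipped$n, clip_p = upd$clipped$p,
    clip_k = upd$clipped$k, clip_soc = upd$clipped$soc,
    stock_n = plots$stock_n, stock_p = plots$stock_p,
    stock_k = plots$stock_k, stock_soc = plots$stock_soc
  )
  world$plots <- plots
  list(world = world,
       ledger = ledger,
       sediment = c(eroded = routed$landscape_eroded,
                    deposited = routed$landscape_deposited))
}

# Collapse one year's plot ledger into long-format records by farm type.
record_year <- function(ledger, scenario, rep) {
  vars <- c(fert_kg_ha = "fert_kg_ha", manure_kg_ha = "manure_kg_ha",
            maize_yield = "maize_yield", legume_yield = "legume_yield",
            balance_n = NA, balance_p = NA, balance_k = NA, balance_c = NA,
            stock_n = "stock_n", stock_p = "stock_p", stock_k = "stock_k",
            stock_c = "stock_soc")
  ledger$balance_n <- ledger$in_n - ledger$out_n
  ledger$balance_p <- ledger$in_p - ledger$out_p
  ledger$balance_k <- ledger$in_k - ledger$out_k
  ledger$balance_c <- ledger$in_c - ledger$out_c
  vars[is.na(vars)] <- names(vars)[is.na(vars)]
  groups <- c(list(all = seq_len(nrow(ledger))),
              split(seq_len(nrow(ledger)), ledger$farm_type))
  recs <- lapply(names(groups), function(g) {
    ix <- groups[[g]]
    data.frame(scenario = scenario, replication = rep,
               year = ledger$year[1], farm_type = g,
               variable = names(vars),
               value = vapply(vars, function(v) mean(ledger[[v]][ix]),
                              numeric(1)),
               row.names = NULL)
  })
  do.call(rbind, recs)
}

#' Run a replicated multi-scenario simulation experiment
#'
#' For each scenario and replication, seeds an isolated RNG stream from the
#' master seed (via [stream_seed()], so results for one scenario never
#' depend on which others are in the batch), draws one coefficient
#' realisation per replication, runs the annual tick over the horizon and
#' records farm-type and population means.
#'
#' @param config configuration from [load_config()].
#' @param scenarios character vector of scenario names.
#' @param world optional pre-built world from [initialise()]; built from
#'   `config` when omitted.
#' @return object of class `simulation_output`: long-format data.frame
#'   (`scenario`, `replication`, `year`, `farm_type`, `variable`, `value`)
#'   with attributes `config_hash`, `seeds`, and — when
#'   `config$record_plots` is `TRUE` — `plot_ledgers` (list of per-run
#'   plot-level ledgers) and `sediment` (per-run yearly landscape budgets).
#' @export
run_experiment <- function(config, scenarios = config$scenario$name,
                           world = NULL) {
  if (is.null(world)) world <- initialise(config)
  records <- list()
  ledgers <- list()
  sediments <- list()
  seeds <- list()
  for (sc in scenarios) {
    schedule <- build_schedule(sc, T_years = config$T,
                               baseline_share = config$scenario$baseline)
    for (rep in seq_len(config$replications)) {
      seed <- stream_seed(config$master_seed, sc, rep)
      seeds[[paste(sc, rep, sep = "/")]] <- seed
      set.seed(seed)
      draws <- if (config$coeff_draw == "none") NULL else
        lapply(world$tables, draw_coefficients, method = config$coeff_draw)
      ec <- if (isTRUE(config$draw_eco) && config$coeff_draw != "none")
        as_eco_params(world$eco, draws = draw_eco_coefficients(
          world$eco, method = if (config$coeff_draw == "uniform")
            "uniform" else "truncnorm"))
      else as_eco_params(world$eco)
      w <- world
      run_ledger <- vector("list", config$T)
      run_sed <- matrix(NA_real_, config$T, 2,
                        dimnames = list(NULL, c("eroded", "deposited")))
      for (t in seq_len(config$T)) {
        stepped <- step_year(w, year = t - 1, s_t = schedule$s[t],
                             draws = draws, ec = ec)
        w <- stepped$world
        run_ledger[[t]] <- stepped$ledger
        run_sed[t, ] <- stepped$sediment
        records[[length(records) + 1]] <-
          record_year(stepped$ledger, sc, rep)
      }
      if (isTRUE(config$record_plots)) {
        key <- paste(sc, rep, sep = "/")
        ledgers[[key]] <- do.call(rbind, run_ledger)
        sediments[[key]] <- run_sed
      }
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  structure(out, class = c("simulation_output", "data.frame"),
            config_hash = attr(config, "hash") %||% config_hash(config),
            seeds = seeds,
            plot_ledgers = if (length(ledgers)) ledgers,
            sediment = if (length(sediments)) sediments)
}

#' @export
print.simulation_output <- function(x, ...) {
  cat("<simulation_output> ", length(unique(x$scenario)), " scenario(s) x ",
      max(x$replication), " replication(s) x ", length(unique(x$year)),
      " year(s); ", nrow(x), " records (config ",
      attr(x, "config_hash") %||% "?", ")\n", sep = "")
  invisible(x)
}

#' Write simulation output and provenance to a directory
#'
#' @param output a `simulation_output`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_output <- function(output, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(output), file.path(dir, "results.csv"),
                   row.names = FALSE)
  prov <- c(paste("config_hash:", attr(output, "config_hash")),
            vapply(names(attr(output, "seeds")), function(k)
              paste0("seed ", k, ": ", attr(output, "seeds")[[k]]),
              character(1)))
  writeLines(prov, file.path(dir, "provenance.txt"))
  invisible(dir)
}
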