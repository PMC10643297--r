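# Synthetic landscape, survey and behavioural ground truth, so the full
# pipeline is testable end to end without any external data. The landscape
# uses summed low-frequency harmonics for relief and Gaussian-filtered white
# noise for spatially autocorrelated soil maps — sufficient spatial
# structure for simulation testing, not a digital-soil-mapping method.

# Separable Gaussian blur with reflective edge padding.
gauss_blur <- function(m, sigma = 3) {
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-half:half, 0, sigma)
  k <- k / sum(k)
  blur_vec <- function(v) {
    n <- length(v)
    pad <- c(v[pmin(n, pmax(1, half:1))], v, v[pmin(n, pmax(1, n - (1:half) + 1))])
    out <- stats::filter(pad, k, sides = 2)
    as.numeric(out[(half + 1):(half + n)])
  }
  m <- apply(m, 2, blur_vec)
  t(apply(m, 1, blur_vec))
}

# percent slope by central differences on a 10 m grid
slope_from_elevation <- function(elev, cellsize = 10) {
  nr <- nrow(elev); nc <- ncol(elev)
  gx <- elev[, pmin(nc, 2:(nc + 1))[1:nc]] - elev[, pmax(1, 0:(nc - 1))]
  span_x <- matrix(rep(ifelse(1:nc == 1 | 1:nc == nc, 1, 2), each = nr), nr, nc)
  gy <- elev[pmin(nr, 2:(nr + 1))[1:nr], ] - elev[pmax(1, 0:(nr - 1)), ]
  span_y <- matrix(rep(ifelse(1:nr == 1 | 1:nr == nr, 1, 2), nc), nr, nc)
  100 * sqrt((gx / (span_x * cellsize))^2 + (gy / (span_y * cellsize))^2)
}

#' Generate a synthetic landscape raster set
#'
#' Smooth random elevation (summed low-frequency harmonics), slope derived
#' from it, spatially autocorrelated nutrient concentration maps
#' (Gaussian-filtered white noise rescaled to the configured mean/sd), clay,
#' bulk density and a cultivated mask covering a configurable fraction.
#'
#' @param nrows,ncols grid dimensions (10 m pixels).
#' @param seed optional RNG seed for reproducibility.
#' @param means,sds named numeric vectors for the soil maps; defaults give
#'   total N 800 mg/kg, P 300 mg/kg, K 1200 mg/kg, SOC 15000 mg/kg (1.5%),
#'   clay 25%, bulk density 1.3 t/m3.
#' @param cultivated_frac fraction of the landscape under cultivation.
#' @param sigma Gaussian filter sd in pixels (spatial correlation length).
#' @param relief relief amplitude in m over the grid.
#' @return named list of matrices: `elevation`, `slope`, `n`, `p`, `k`,
#'   `soc`, `clay`, `bulk_density`, `mask` (logical), plus `cellsize`.
#' @export
gen_landscape <- function(nrows, ncols, seed = NULL,
                          means = c(n = 800, p = 300, k = 1200, soc = 15000,
                                    clay = 25, bulk_density = 1.3),
                          sds = c(n = 150, p = 60, k = 250, soc = 3000,
                                  clay = 5, bulk_density = 0.08),
                          cultivated_frac = 0.6, sigma = 3, relief = 80) {
  if (!is.null(seed)) set.seed(seed)
  rr <- (seq_len(nrows) - 1) / nrows
  cc <- (seq_len(ncols) - 1) / ncols
  elev <- matrix(0, nrows, ncols)
  for (h in 1:5) {
    fr <- stats::runif(1, 0.5, 3); fc <- stats::runif(1, 0.5, 3)
    ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
    elev <- elev + outer(sin(2 * pi * fr * rr + ph1),
                         cos(2 * pi * fc * cc + ph2)) / h
  }
  elev <- 1000 + relief * (elev - min(elev)) / diff(range(elev)) +
    matrix(stats::rnorm(nrows * ncols, 0, 0.05), nrows, ncols)
  corr_field <- function(mean, sd, positive = TRUE) {
    z <- gauss_blur(matrix(stats::rnorm(nrows * ncols), nrows, ncols), sigma)
    z <- (z - mean(z)) / stats::sd(z)
    f <- mean + sd * z
    if (positive) f <- pmax(f, mean * 0.05)
    f
  }
  maps <- lapply(names(means), function(v) corr_field(means[[v]], sds[[v]]))
  names(maps) <- names(means)
  suit <- gauss_blur(matrix(stats::rnorm(nrows * ncols), nrows, ncols), sigma * 2)
  mask <- suit <= stats::quantile(suit, cultivated_frac)
  c(list(elevation = elev, slope = slope_from_elevation(elev),
         mask = mask, cellsize = 10), maps)
}

#' Generate a survey-like household and plot sample
#'
#' Households are drawn across the three farm types with type-dependent
#' attribute distributions (higher income, livestock and input use for type
#' 3); plots are nested in households, placed contiguously on the cultivated
#' mask by region growing, and take their slope and clay from the landscape.
#'
#' @param landscape raster set from [gen_landscape()].
#' @param n_households sample size (default 250).
#' @param mean_plots_per_hh mean plots per household; the default Poisson
#'   rate 1.6 with a floor of one plot yields about 1.8 plots per household
#'   (roughly 451 plots for 250 households).
#' @param type_props farm-type proportions (low, medium, high input).
#' @param seed optional RNG seed.
#' @return list: `households`, `plots`, `plot_map` (matrix of plot row
#'   indices).
#' @export
gen_survey <- function(landscape, n_households = 250, mean_plots_per_hh = 1.6,
                       type_props = c(0.45, 0.35, 0.20), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ft <- base::sample(1:3, n_households, replace = TRUE, prob = type_props)
  income_mean <- c(250, 450, 900)[ft] * 1000
  livestock_mean <- c(0.5, 1.5, 3.0)[ft]
  households <- data.frame(
    household_id = paste0("hh_", seq_len(n_households)),
    farm_type = ft,
    head_age = round(clamp(stats::rnorm(n_households, 45, 12), 20, 85)),
    head_gender = base::sample(c("male", "female"), n_households, TRUE,
                               prob = c(0.75, 0.25)),
    education = stats::rpois(n_households, 4 + ft),
    labour = round(clamp(stats::rgamma(n_households, shape = 4, scale = 0.6),
                         1, 8), 1),
    income = round(stats::rlnorm(n_households, log(income_mean), 0.5)),
    livestock = round(stats::rgamma(n_households, shape = 1.5,
                                    scale = livestock_mean / 1.5), 2),
    group_membership = stats::runif(n_households) < 0.2 + 0.1 * ft,
    transport_access = stats::runif(n_households) < 0.3,
    communication_access = stats::runif(n_households) < 0.6,
    sampled = TRUE,
    stringsAsFactors = FALSE
  )
  nr <- nrow(landscape$mask); nc <- ncol(landscape$mask)
  free <- as.vector(landscape$mask)
  plot_map <- matrix(NA_integer_, nr, nc)
  rows <- list()
  idx <- 0
  for (h in seq_len(n_households)) {
    n_plots <- max(1, stats::rpois(1, mean_plots_per_hh))
    for (p in seq_len(n_plots)) {
      area <- stats::rlnorm(1, log(0.25), 0.4)
      npix <- max(1L, as.integer(round(area / 0.01)))
      avail <- which(free)
      if (!length(avail)) stop("cultivated mask exhausted while sampling plots")
      seed_px <- avail[base::sample.int(length(avail), 1)]
      px <- grow_plot(free, nr, nc, seed_px, npix)
      free[px] <- FALSE
      idx <- idx + 1
      legume <- stats::runif(1) < 0.33
      legume_frac <- if (legume) stats::runif(1, 0.1, 0.4) else 0
      fallow_frac <- if (stats::runif(1) < 0.1) stats::runif(1, 0.1, 0.3) else 0
      retained_mean <- c(0.3, 0.5, 0.7)[households$farm_type[h]]
      rows[[idx]] <- data.frame(
        plot_id = paste0("pl_", idx),
        household_id = households$household_id[h],
        row = ((px[1] - 1) %% nr) + 1,
        col = ((px[1] - 1) %/% nr) + 1,
        npix = length(px),
        area_ha = length(px) * 0.01,
        slope = mean(landscape$slope[px]),
        clay = mean(landscape$clay[px]),
        tpi = base::sample(1:3, 1),
        cultivation_period = stats::rpois(1, 8),
        swc_flag = stats::runif(1) < 0.15,
        maize_frac = max(0, 1 - legume_frac - fallow_frac),
        legume_frac = legume_frac,
        fallow_frac = fallow_frac,
        residue_retained_fraction = clamp(stats::rbeta(1, 2, 2) *
                                            retained_mean * 2, 0, 1),
        stringsAsFactors = FALSE
      )
      plot_map[px] <- idx
    }
  }
  plots <- do.call(rbind, rows)
  validate_households(households)
  validate_plots(plots, households)
  list(households = households, plots = plots, plot_map = plot_map)
}

#' Generate double-hurdle ground truth and decision records
#'
#' Draws true coefficient tables for a fertilizer adoption/intensity pair —
#' subsidy coefficient positive on adoption per the programme-impact
#' hypothesis — and simulates decision records from the exact two-hurdle
#' process: a Bernoulli adoption gate at `logistic(b1'x)` and, for
#' adopters, a log-normal amount `exp(b2'x + e)`, `e ~ N(0, sigma)`.
#'
#' @param n number of decision records (default 2000).
#' @param seed optional RNG seed.
#' @param sigma log-scale residual sd of the intensity process.
#' @return list: `tables` (true [coefficient_table] pair), `data`
#'   (data.frame `amount`, `subsidy_share`, `livestock_tlu`, `education`),
#'   `sigma`.
#' @export
gen_behavioural_truth <- function(n = 2000, seed = NULL, sigma = 0.4) {
  if (!is.null(seed)) set.seed(seed)
  b1 <- c(intercept = stats::runif(1, -0.5, 0.5),
          subsidy_share = stats::runif(1, 0.8, 1.6),
          livestock_tlu = stats::runif(1, 0.02, 0.10),
          education = stats::runif(1, 0.01, 0.06))
  b2 <- c(intercept = stats::runif(1, 3.5, 4.2),
          subsidy_share = stats::runif(1, 0.3, 0.7),
          livestock_tlu = stats::runif(1, 0.02, 0.08),
          education = stats::runif(1, 0.005, 0.03))
  x <- data.frame(
    subsidy_share = stats::runif(n, 0, 0.7),
    livestock_tlu = stats::rgamma(n, shape = 1.5, scale = 1),
    education = stats::rpois(n, 6)
  )
  xm <- cbind(intercept = 1, as.matrix(x))
  p <- stats::plogis(as.vector(xm %*% b1))
  gate <- stats::runif(n) < p
  amount <- ifelse(gate, exp(as.vector(xm %*% b2) +
                               stats::rnorm(n, 0, sigma)), 0)
  tables <- list(
    adopt_fert = coefficient_table("adopt_fert", b1, link = "logit",
                                   bounds = c(0, 1)),
    qty_fert = coefficient_table("qty_fert", b2, link = "log",
                                 bounds = c(0, Inf))
  )
  list(tables = tables, data = cbind(data.frame(amount = amount), x),
       sigma = sigma)
}

#' Write a complete ready-to-run synthetic input directory
#'
#' Generates a landscape, a survey sample, coefficient tables (the shipped
#' defaults) and a configuration file, in exactly the formats the readers
#' and [initialise()] consume.
#'
#' @param dir output directory (created).
#' @param nrows,ncols landscape grid size.
#' @param n_households survey sample size.
#' @param seed RNG seed for the generators.
#' @param config_overrides named list merged into the written config
#'   (e.g. `list(population = list(sampled_fraction = 0.3))`).
#' @return the configuration file path, invisibly.
#' @export
gen_synthetic_inputs <- function(dir, nrows = 400, ncols = 400,
                                 n_households = 250, seed = 1,
                                 config_overrides = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  land <- gen_landscape(nrows, ncols, seed = seed)
  survey <- gen_survey(land, n_households = n_households, seed = seed + 1)
  for (v in c("elevation", "clay", "bulk_density", "n", "p", "k", "soc")) {
    write_raster(land[[v]], file.path(dir, paste0(v, ".asc")))
  }
  write_raster(land$mask * 1, file.path(dir, "mask.asc"))
  pm <- survey$plot_map
  write_raster(pm, file.path(dir, "plot_map.asc"))
  write_survey(survey, dir)
  write_coefficients(default_coefficient_tables(),
                     file.path(dir, "coefficients.csv"))
  utils::write.csv(default_eco_coefficients(),
                   file.path(dir, "eco_coefficients.csv"), row.names = FALSE)
  cfg <- merge_config(default_config(), config_overrides)
  cfg$input_dir <- dir
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], cfg_path)
  invisible(cfg_path)
}
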