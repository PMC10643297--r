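# Shared fixtures, built in code at test time.

# Point-estimate eco parameters with selective overrides.
eco_params <- function(...) {
  ec <- massai::as_eco_params(massai::default_eco_coefficients())
  over <- c(...)
  if (length(over)) ec[names(over)] <- over
  ec
}

# A small ready-to-run synthetic input directory (cached per session).
.fixture_env <- new.env(parent = emptyenv())

small_input_dir <- function() {
  if (is.null(.fixture_env$dir)) {
    dir <- file.path(tempdir(), "massai-small-world")
    massai::gen_synthetic_inputs(
      dir, nrows = 60, ncols = 60, n_households = 25, seed = 11,
      config_overrides = list(
        population = list(sampled_fraction = 0.4),
        replications = 2, T = 5, record_plots = TRUE))
    .fixture_env$dir <- dir
  }
  .fixture_env$dir
}

small_config <- function(overrides = list()) {
  massai::load_config(file.path(small_input_dir(), "config.yaml"),
                      overrides = overrides)
}

small_world <- function() {
  if (is.null(.fixture_env$world)) {
    .fixture_env$world <- massai::initialise(small_config())
  }
  .fixture_env$world
}

# The study-scale world for the deep acceptance checks: a 100 x 100 grid
# whose upscaled population runs 2 scenarios x 3 replications x 20 years.
acceptance_input_dir <- function() {
  if (is.null(.fixture_env$acc_dir)) {
    dir <- file.path(tempdir(), "massai-acceptance-world")
    massai::gen_synthetic_inputs(
      dir, nrows = 100, ncols = 100, n_households = 50, seed = 7,
      config_overrides = list(
        population = list(sampled_fraction = 0.3),
        replications = 3, T = 20, record_plots = TRUE))
    .fixture_env$acc_dir <- dir
  }
  .fixture_env$acc_dir
}

acceptance_run <- function() {
  if (is.null(.fixture_env$acc_out)) {
    cfg <- massai::load_config(file.path(acceptance_input_dir(),
                                         "config.yaml"))
    world <- massai::initialise(cfg)
    .fixture_env$acc_world <- world
    .fixture_env$acc_out <- massai::run_experiment(
      cfg, scenarios = c("zero", "universal"), world = world)
  }
  list(world = .fixture_env$acc_world, output = .fixture_env$acc_out)
}

# Max |X_{t+1} - X_t - clipped - (sum IN - sum OUT)| over a plot ledger
# (clipped deficits are logged as positive magnitudes), seeded with the
# initial stocks from the world.
conservation_residual <- function(ledger, world) {
  pools <- c(n = "n", p = "p", k = "k", soc = "c")
  worst <- 0
  for (pid in unique(ledger$plot_id)) {
    d <- ledger[ledger$plot_id == pid, ]
    d <- d[order(d$year), ]
    w <- world$plots[world$plots$plot_id == pid, ]
    for (pool in names(pools)) {
      nut <- pools[[pool]]
      stock_col <- paste0("stock_", pool)
      clip_col <- if (pool == "soc") "clip_soc" else paste0("clip_", pool)
      prev <- c(w[[stock_col]], utils::head(d[[stock_col]], -1))
      resid <- d[[stock_col]] - prev - d[[clip_col]] -
        (d[[paste0("in_", nut)]] - d[[paste0("out_", nut)]])
      worst <- max(worst, max(abs(resid)))
    }
  }
  worst
}
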