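# Structured simulation configuration: defaults, validation, canonical hash.

#' Default simulation configuration
#'
#' @return named list of all configuration keys with their defaults: a
#'   20-year horizon, 10 replications, the current-subsidy scenario at the
#'   0.28 baseline share, 900 mm annual rainfall, a 0.10 m managed layer and
#'   truncated-normal per-replication coefficient draws.
#' @export
default_config <- function() {
  list(
    input_dir = NULL,
    output_dir = NULL,
    T = 20,
    replications = 10,
    master_seed = 1,
    progressive = TRUE,
    rain_mm = 900,
    depth_m = 0.10,
    coarse_fragments = 0.05,
    coeff_draw = "truncnorm",   # truncnorm | uniform | none
    draw_eco = TRUE,
    fert_product = "npk_23_21_0",
    record_plots = FALSE,
    scenario = list(name = "current", baseline = 0.28, custom_path = NULL),
    population = list(synthesize = TRUE, sampled_fraction = 0.171,
                      jitter_sd_frac = 0.10)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (cfg$replications < 1) stop("config: replications must be >= 1")
  if (cfg$T < 1) stop("config: T must be >= 1")
  if (cfg$depth_m <= 0) stop("config: depth_m must be > 0")
  if (cfg$coarse_fragments < 0 || cfg$coarse_fragments >= 1)
    stop("config: coarse_fragments must be in [0, 1)")
  if (!cfg$coeff_draw %in% c("truncnorm", "uniform", "none"))
    stop("config: coeff_draw must be truncnorm, uniform or none")
  if (!cfg$scenario$name %in% c("current", "reduced", "zero", "universal"))
    stop("config: unknown scenario name ", cfg$scenario$name)
  sf <- cfg$population$sampled_fraction
  if (sf <= 0 || sf > 1) stop("config: sampled_fraction must be in (0, 1]")
  cfg
}

#' Load and validate a simulation configuration
#'
#' Reads a YAML file, fills in [default_config()] defaults, rejects unknown
#' keys and validates values. The fully-resolved configuration carries a
#' canonical hash (stable under key reordering) as attribute `hash`, which
#' is recorded with every simulation output for provenance.
#'
#' @param path YAML file; an empty file yields all defaults.
#' @param overrides optional named list applied on top of the file
#'   (same validation).
#' @return validated configuration list with attribute `hash`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  user <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path) %||% list()
  } else list()
  cfg <- merge_config(default_config(), user)
  cfg <- merge_config(cfg, overrides)
  cfg <- validate_config(cfg)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Canonical hash of a configuration
#'
#' @param cfg configuration list.
#' @return 8-hex-digit hash string, invariant to key ordering.
#' @export
config_hash <- function(cfg) {
  attributes(cfg) <- attributes(cfg)["names"]
  canonical_hash(cfg)
}
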