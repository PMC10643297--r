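# CSV schemas and validated readers for survey tables and coefficient
# tables. Readers reject on schema violations rather than coercing; column
# schemas are documented in FORMATS.md at the repository root.

HOUSEHOLD_COLS <- c("household_id", "farm_type", "head_age", "head_gender",
                    "education", "labour", "income", "livestock",
                    "group_membership", "transport_access",
                    "communication_access", "sampled")

PLOT_COLS <- c("plot_id", "household_id", "row", "col", "npix", "area_ha",
               "slope", "clay", "tpi", "cultivation_period", "swc_flag",
               "maize_frac", "legume_frac", "fallow_frac",
               "residue_retained_fraction")

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " table is missing column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}

#' Validate a household table
#'
#' @param households data.frame with the household schema.
#' @return the table, invisibly; errors on violations.
#' @export
validate_households <- function(households) {
  check_cols(households, HOUSEHOLD_COLS, "household")
  if (anyDuplicated(households$household_id))
    stop("duplicate household ids")
  if (!all(households$farm_type %in% 1:3))
    stop("farm_type must be 1, 2 or 3")
  if (any(households$head_age <= 0)) stop("head_age must be > 0")
  invisible(households)
}

#' Validate a plot table against its household table
#'
#' @param plots data.frame with the plot schema.
#' @param households validated household table.
#' @return the table, invisibly; errors on violations (including orphan
#'   plots referencing unknown households).
#' @export
validate_plots <- function(plots, households) {
  check_cols(plots, PLOT_COLS, "plot")
  orphans <- setdiff(plots$household_id, households$household_id)
  if (length(orphans))
    stop("orphan plots: household(s) not found: ",
         paste(orphans, collapse = ", "))
  if (any(plots$area_ha <= 0)) stop("area_ha must be > 0")
  if (any(plots$cultivation_period < 0)) stop("cultivation_period must be >= 0")
  fr <- plots$maize_frac + plots$legume_frac + plots$fallow_frac
  if (any(plots$maize_frac < 0 | plots$legume_frac < 0 | plots$fallow_frac < 0 |
            fr > 1 + 1e-9))
    stop("crop allocation fractions must be in [0, 1] and sum to <= 1")
  if (any(plots$residue_retained_fraction < 0 |
            plots$residue_retained_fraction > 1))
    stop("residue_retained_fraction must be in [0, 1]")
  invisible(plots)
}

#' Read household and plot survey tables from a directory
#'
#' Expects `households.csv` and `plots.csv` (UTF-8, header row) with the
#' schemas documented in FORMATS.md; both are schema-validated and checked
#' for referential integrity.
#'
#' @param dir directory containing the two files.
#' @return list with validated `households` and `plots` data.frames.
#' @export
read_survey <- function(dir) {
  hh_path <- file.path(dir, "households.csv")
  pl_path <- file.path(dir, "plots.csv")
  for (p in c(hh_path, pl_path))
    if (!file.exists(p)) stop("survey file not found: ", p)
  households <- utils::read.csv(hh_path, stringsAsFactors = FALSE)
  plots <- utils::read.csv(pl_path, stringsAsFactors = FALSE)
  households$group_membership <- as.logical(households$group_membership)
  households$transport_access <- as.logical(households$transport_access)
  households$communication_access <- as.logical(households$communication_access)
  households$sampled <- as.logical(households$sampled)
  plots$swc_flag <- as.logical(plots$swc_flag)
  validate_households(households)
  validate_plots(plots, households)
  list(households = households, plots = plots)
}

#' Write survey tables in the schema the reader consumes
#'
#' @param survey list with `households` and `plots`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(survey$households[, HOUSEHOLD_COLS],
                   file.path(dir, "households.csv"), row.names = FALSE)
  utils::write.csv(survey$plots[, PLOT_COLS],
                   file.path(dir, "plots.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read behavioural coefficient tables from CSV
#'
#' `path` holds rows `model, predictor, estimate, ci_lo, ci_hi`;
#' `models_path` declares `model, link, bound_min, bound_max` per model.
#'
#' @param path coefficients CSV.
#' @param models_path models CSV; defaults to `models.csv` next to `path`.
#' @return named list of [coefficient_table]s.
#' @export
read_coefficients <- function(path, models_path = file.path(dirname(path),
                                                            "models.csv")) {
  for (p in c(path, models_path))
    if (!file.exists(p)) stop("coefficient file not found: ", p)
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(co, c("model", "predictor", "estimate", "ci_lo", "ci_hi"),
             "coefficients")
  bad <- co$ci_lo > co$estimate | co$estimate > co$ci_hi
  if (any(bad))
    stop("coefficient rows violate ci_lo <= estimate <= ci_hi: ",
         paste(paste(co$model[bad], co$predictor[bad], sep = ":"),
               collapse = ", "))
  mo <- utils::read.csv(models_path, stringsAsFactors = FALSE)
  check_cols(mo, c("model", "link", "bound_min", "bound_max"), "models")
  tables <- lapply(unique(co$model), function(m) {
    rows <- co[co$model == m, ]
    meta <- mo[mo$model == m, ]
    if (nrow(meta) != 1) stop("models.csv must declare model '", m, "' once")
    coefficient_table(m, stats::setNames(rows$estimate, rows$predictor),
                      ci_lo = rows$ci_lo, ci_hi = rows$ci_hi,
                      link = meta$link, bounds = c(meta$bound_min, meta$bound_max))
  })
  stats::setNames(tables, unique(co$model))
}

#' Write behavioural coefficient tables to CSV
#'
#' @param tables named list of [coefficient_table]s.
#' @param path coefficients CSV path; `models.csv` is written alongside.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(tables, path) {
  co <- do.call(rbind, lapply(tables, function(t)
    data.frame(model = attr(t, "model"), predictor = t$predictor,
               estimate = t$estimate, ci_lo = t$ci_lo, ci_hi = t$ci_hi)))
  mo <- do.call(rbind, lapply(tables, function(t)
    data.frame(model = attr(t, "model"), link = attr(t, "link"),
               bound_min = attr(t, "bounds")[1],
               bound_max = attr(t, "bounds")[2])))
  utils::write.csv(co, path, row.names = FALSE)
  utils::write.csv(mo, file.path(dirname(path), "models.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read an ecological coefficient table from CSV
#'
#' Expects columns `name, estimate, lo, hi, units`; interval bounds must
#' bracket the estimate.
#'
#' @param path CSV path.
#' @return data.frame in the [default_eco_coefficients()] layout.
#' @export
read_eco_coefficients <- function(path) {
  if (!file.exists(path)) stop("eco coefficient file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("name", "estimate", "lo", "hi"), "eco coefficients")
  if (any(df$lo > df$estimate | df$estimate > df$hi))
    stop("eco coefficient rows violate lo <= estimate <= hi")
  df
}
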