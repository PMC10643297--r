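# Farmer decision models: double-hurdle adoption/intensity for each soil
# fertility management practice, a bounded GLM yield predictor, stochastic
# coefficient realisation within confidence intervals, and the estimation
# harness that recovers coefficient tables from decision data.

MODEL_NAMES <- c("adopt_fert", "qty_fert", "adopt_manure", "qty_manure",
                 "adopt_legume", "share_legume", "adopt_swc",
                 "yield_maize", "yield_legume")

#' Construct a behavioural coefficient table
#'
#' One table per sub-model: named predictors with point estimates and
#' confidence-interval bounds, a link function for the predicted outcome and
#' outcome bounds.
#'
#' @param model model name, one of `r paste(MODEL_NAMES, collapse = ", ")`.
#' @param estimates named numeric vector of coefficient point estimates
#'   (include an `intercept` entry for the constant term).
#' @param ci_lo,ci_hi confidence-interval bounds, same names/order as
#'   `estimates`; must bracket the estimate. Defaults collapse to the
#'   estimate (degenerate interval).
#' @param link link for the predicted outcome: `"logit"`, `"log"` or
#'   `"identity"`.
#' @param bounds length-2 numeric, clamp interval for the predicted outcome.
#' @return object of class `coefficient_table`.
#' @export
coefficient_table <- function(model, estimates, ci_lo = estimates,
                              ci_hi = estimates,
                              link = c("logit", "log", "identity"),
                              bounds = c(0, Inf)) {
  model <- match.arg(model, MODEL_NAMES)
  link <- match.arg(link)
  stopifnot(!is.null(names(estimates)), length(ci_lo) == length(estimates),
            length(ci_hi) == length(estimates), length(bounds) == 2)
  if (any(ci_lo > estimates | estimates > ci_hi))
    stop("coefficient_table: need ci_lo <= estimate <= ci_hi")
  if (bounds[1] > bounds[2]) stop("coefficient_table: bounds.min > bounds.max")
  structure(
    data.frame(predictor = names(estimates), estimate = unname(estimates),
               ci_lo = unname(ci_lo), ci_hi = unname(ci_hi),
               stringsAsFactors = FALSE),
    model = model, link = link, bounds = bounds,
    class = c("coefficient_table", "data.frame")
  )
}

#' @export
print.coefficient_table <- function(x, ...) {
  cat("<coefficient_table ", attr(x, "model"), "> link=", attr(x, "link"),
      " bounds=[", attr(x, "bounds")[1], ", ", attr(x, "bounds")[2], "]\n",
      sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

link_inverse <- function(link) {
  switch(link, logit = stats::plogis, log = exp, identity = identity,
         stop("unknown link: ", link))
}

#' Draw one realised coefficient vector from a table
#'
#' Each coefficient is drawn from `Normal(estimate, (ci_hi - ci_lo) /
#' (2 * 1.96))` truncated to `[ci_lo, ci_hi]`; a degenerate interval returns
#' the estimate. Draw once per replication and hold fixed within it, so a
#' run is internally coherent while runs express parameter uncertainty.
#'
#' @param table a [coefficient_table].
#' @param method `"truncnorm"` (default) or `"uniform"` on the interval;
#'   `"none"` returns the point estimates.
#' @return named numeric coefficient vector.
#' @export
draw_coefficients <- function(table, method = c("truncnorm", "uniform", "none")) {
  method <- match.arg(method)
  est <- table$estimate; lo <- table$ci_lo; hi <- table$ci_hi
  vals <- switch(method,
    none = est,
    uniform = ifelse(hi > lo, stats::runif(length(est), lo, hi), est),
    truncnorm = mapply(function(e, l, h)
      rtruncnorm(1, e, (h - l) / (2 * 1.96), l, h), est, lo, hi)
  )
  stats::setNames(vals, table$predictor)
}

#' Assemble the decision context for a set of plots
#'
#' Joins household attributes onto plots and derives the predictor columns
#' the shipped coefficient tables use (scaled income, farm-type indicators,
#' soil stocks per 100 kg/ha, the subsidy share, and any cross-practice
#' linkage flags supplied via `extra`).
#'
#' @param households household table (see [read_survey()] schema).
#' @param plots plot table; one row per plot.
#' @param s_t subsidy share for the year, in `[0, 1]`.
#' @param extra named list of additional predictor columns (e.g.
#'   `legume_planted`, `fert_kg_100`, `manure_t`), each scalar or one value
#'   per plot.
#' @return data.frame with one row per plot, columns named as predictors.
#' @export
build_context <- function(households, plots, s_t, extra = list()) {
  i <- match(plots$household_id, households$household_id)
  if (anyNA(i)) stop("plots reference unknown households: ",
                     paste(unique(plots$household_id[is.na(i)]), collapse = ", "))
  hh <- households[i, ]
  ctx <- data.frame(
    intercept = 1,
    subsidy_share = s_t,
    head_age = hh$head_age,
    education = hh$education,
    labour = hh$labour,
    income_1000 = hh$income / 1000,
    livestock_tlu = hh$livestock,
    group_membership = as.numeric(hh$group_membership),
    transport_access = as.numeric(hh$transport_access),
    communication_access = as.numeric(hh$communication_access),
    farm_type2 = as.numeric(hh$farm_type == 2),
    farm_type3 = as.numeric(hh$farm_type == 3),
    slope_pct = plots$slope,
    clay_pct = plots$clay,
    tpi = plots$tpi,
    cultivation_period = plots$cultivation_period,
    area_ha = plots$area_ha,
    soil_n_100 = plots$stock_n / 100,
    soil_p_100 = plots$stock_p / 100,
    soil_k_100 = plots$stock_k / 100,
    soil_soc_1000 = plots$stock_soc / 1000
  )
  for (nm in names(extra)) ctx[[nm]] <- extra[[nm]]
  ctx
}

# linear predictor beta'x with informative failure on missing predictors
linear_predictor <- function(ctx, beta) {
  missing <- setdiff(names(beta), names(ctx))
  if (length(missing))
    stop("decision context is missing predictor(s): ",
         paste(missing, collapse = ", "))
  as.vector(as.matrix(ctx[, names(beta), drop = FALSE]) %*% beta)
}

#' Two-hurdle decision: adoption gate then conditional intensity
#'
#' Hurdle one: adoption probability `p = logistic(beta1'x)`, realised as a
#' Bernoulli draw so population adoption rates match predicted probabilities
#' in expectation. Hurdle two (adopters only): amount
#' `clamp(g^{-1}(beta2'x), bounds)` with `g` the intensity table's link.
#'
#' @param ctx decision context (one row per plot), from [build_context()].
#' @param adopt_table [coefficient_table] for the adoption logit.
#' @param qty_table [coefficient_table] for the intensity model.
#' @param adopt_draw,qty_draw optional realised coefficient vectors (from
#'   [draw_coefficients()]); defaults to the point estimates.
#' @return list: `p` (adoption probabilities), `adopted` (logical),
#'   `amount` (kg/ha or outcome units; 0 for non-adopters).
#' @export
hurdle_decision <- function(ctx, adopt_table, qty_table,
                            adopt_draw = NULL, qty_draw = NULL) {
  b1 <- adopt_draw %||% stats::setNames(adopt_table$estimate, adopt_table$predictor)
  b2 <- qty_draw %||% stats::setNames(qty_table$estimate, qty_table$predictor)
  p <- stats::plogis(linear_predictor(ctx, b1))
  adopted <- stats::runif(nrow(ctx)) < p
  inv <- link_inverse(attr(qty_table, "link"))
  bounds <- attr(qty_table, "bounds")
  amount <- ifelse(adopted, clamp(inv(linear_predictor(ctx, b2)),
                                  bounds[1], bounds[2]), 0)
  list(p = p, adopted = adopted, amount = amount)
}

#' All per-plot management decisions for one year
#'
#' Evaluation order is legume, fertilizer, manure, then conservation, so the
#' legume-planted linkage flag exists when the fertilizer model needs it.
#' The subsidy share enters the fertilizer (and other) models wherever their
#' tables name the `subsidy_share` predictor.
#'
#' @param households,plots survey tables (plots carry current soil stocks).
#' @param s_t subsidy share for the year.
#' @param tables named list of [coefficient_table]s covering
#'   `adopt_fert`, `qty_fert`, `adopt_manure`, `qty_manure`, `adopt_legume`,
#'   `share_legume`, `adopt_swc`.
#' @param draws optional named list of realised coefficient vectors per
#'   model.
#' @return data.frame, one row per plot: `plot_id`, `fert_kg_ha`,
#'   `subsidised_share`, `manure_kg_ha`, `legume_fraction`,
#'   `residue_retained_fraction`, `swc_flag`.
#' @export
decide_all <- function(households, plots, s_t, tables, draws = NULL) {
  dr <- function(m) draws[[m]] %||% NULL
  ctx <- build_context(households, plots, s_t)

  leg <- hurdle_decision(ctx, tables$adopt_legume, tables$share_legume,
                         dr("adopt_legume"), dr("share_legume"))
  legume_fraction <- clamp(leg$amount, 0, 1)
  # legume area cannot exceed the non-fallow land not needed for maize floor
  legume_fraction <- pmin(legume_fraction, 1 - plots$fallow_frac)

  ctx$legume_planted <- as.numeric(legume_fraction > 0)
  fert <- hurdle_decision(ctx, tables$adopt_fert, tables$qty_fert,
                          dr("adopt_fert"), dr("qty_fert"))
  man <- hurdle_decision(ctx, tables$adopt_manure, tables$qty_manure,
                         dr("adopt_manure"), dr("qty_manure"))

  b_swc <- dr("adopt_swc") %||%
    stats::setNames(tables$adopt_swc$estimate, tables$adopt_swc$predictor)
  p_swc <- stats::plogis(linear_predictor(ctx, b_swc))
  swc_new <- stats::runif(nrow(ctx)) < p_swc
  data.frame(
    plot_id = plots$plot_id,
    fert_kg_ha = fert$amount,
    subsidised_share = ifelse(fert$amount > 0, s_t, 0),
    manure_kg_ha = man$amount,
    legume_fraction = legume_fraction,
    residue_retained_fraction = plots$residue_retained_fraction,
    swc_flag = plots$swc_flag | swc_new  # structures persist once built
  )
}

#' Predict a bounded crop yield
#'
#' `yield = clamp(g^{-1}(beta'x), bounds)` with predictors covering the
#' household livelihood profile, land productivity (soil stocks, slope,
#' cultivation period) and the decided inputs.
#'
#' @param ctx decision context including decided-input columns the table
#'   names (e.g. `fert_kg_100`, `manure_t`).
#' @param table [coefficient_table] for `yield_maize` or `yield_legume`.
#' @param draw optional realised coefficient vector.
#' @return yield in kg/ha (vector, one per context row).
#' @export
predict_yield <- function(ctx, table, draw = NULL) {
  beta <- draw %||% stats::setNames(table$estimate, table$predictor)
  inv <- link_inverse(attr(table, "link"))
  bounds <- attr(table, "bounds")
  clamp(inv(linear_predictor(ctx, beta)), bounds[1], bounds[2])
}

#' Winsorise predictions to baseline limits and correct model drift
#'
#' Predictions are clipped to the `p_lo`/`p_hi` order-statistic quantiles of
#' the baseline (type-1 quantiles, so a prediction set identical to the
#' baseline passes through unchanged), then rescaled by the drift
#' coefficient `mean(baseline) / mean(predictions)` so the adjusted series
#' is anchored to observed farm conditions.
#'
#' @param predictions numeric vector of model predictions.
#' @param baseline numeric vector of observed baseline values.
#' @param p_lo,p_hi winsorisation percentiles (defaults 0.01 / 0.99).
#' @return adjusted numeric vector, with the drift coefficient attached as
#'   attribute `drift`.
#' @export
winsorise_drift_adjust <- function(predictions, baseline,
                                   p_lo = 0.01, p_hi = 0.99) {
  stopifnot(length(baseline) > 0, p_lo <= p_hi)
  q <- stats::quantile(baseline, c(p_lo, p_hi), type = 1, names = FALSE)
  drift <- mean(baseline) / mean(predictions)
  out <- clamp(predictions, q[1], q[2]) * drift
  attr(out, "drift") <- drift
  out
}

#' Fit a double-hurdle model from decision records
#'
#' Hurdle one is a binomial logit on the adoption indicator
#' (`amount > 0`); hurdle two models the positive amounts — on the log scale
#' (log-normal intensity, the default for positive right-skewed amounts) or
#' on the identity scale. Returns Wald confidence intervals, ready to use as
#' simulation coefficient tables.
#'
#' @param formula model formula, `amount ~ predictors`.
#' @param data data.frame of decision records; the response is the observed
#'   amount with exact zeros for non-adopters.
#' @param link intensity link, `"log"` (default) or `"identity"`.
#' @param min_n minimum number of records required (default 50).
#' @param conf_level confidence level for the Wald intervals.
#' @return object of class `double_hurdle` with components `adoption` (the
#'   binomial [stats::glm] fit), `intensity` (the [stats::lm] fit on
#'   adopters), `link`, `n`, `n_adopters`.
#' @export
fit_double_hurdle <- function(formula, data, link = c("log", "identity"),
                              min_n = 50, conf_level = 0.95) {
  link <- match.arg(link)
  if (nrow(data) < min_n)
    stop("fit_double_hurdle: need at least ", min_n, " records, got ", nrow(data))
  response <- all.vars(formula)[1]
  amount <- data[[response]]
  if (any(amount < 0)) stop("amounts must be >= 0")
  data$.adopted <- as.numeric(amount > 0)
  rhs <- stats::reformulate(attr(stats::terms(formula, data = data), "term.labels"),
                            response = ".adopted")
  separation <- FALSE
  adoption <- withCallingHandlers(
    stats::glm(rhs, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (separation || any(abs(stats::coef(adoption)) > 20))
    stop("fit_double_hurdle: perfect separation detected in the adoption hurdle")
  pos <- data[amount > 0, , drop = FALSE]
  if (nrow(pos) < length(attr(stats::terms(formula, data = data), "term.labels")) + 2)
    stop("fit_double_hurdle: too few adopters to fit the intensity hurdle")
  int_formula <- if (link == "log") {
    stats::update(formula, log(.) ~ .)
  } else formula
  intensity <- stats::lm(int_formula, data = pos)
  structure(list(adoption = adoption, intensity = intensity, link = link,
                 n = nrow(data), n_adopters = nrow(pos),
                 conf_level = conf_level, call = match.call()),
            class = "double_hurdle")
}

#' @export
print.double_hurdle <- function(x, ...) {
  cat("Double-hurdle model (", x$n, " records, ", x$n_adopters,
      " adopters; intensity link: ", x$link, ")\n", sep = "")
  cat("\nAdoption hurdle (logit):\n")
  print(stats::coef(x$adoption))
  cat("\nIntensity hurdle:\n")
  print(stats::coef(x$intensity))
  invisible(x)
}

#' @export
coef.double_hurdle <- function(object, ...) {
  list(adoption = stats::coef(object$adoption),
       intensity = stats::coef(object$intensity))
}

#' @export
confint.double_hurdle <- function(object, parm, level = 0.95, ...) {
  wald <- function(fit) {
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    z <- stats::qnorm(1 - (1 - level) / 2)
    cbind(lo = est - z * se, hi = est + z * se)
  }
  list(adoption = wald(object$adoption), intensity = wald(object$intensity))
}

#' @export
summary.double_hurdle <- function(object, ...) {
  list(adoption = summary(object$adoption), intensity = summary(object$intensity))
}

#' Convert a fitted double hurdle into simulation coefficient tables
#'
#' @param fit a [fit_double_hurdle()] result.
#' @param model_adopt,model_qty model names for the two tables.
#' @param bounds outcome bounds for the intensity table.
#' @return named list of two [coefficient_table]s.
#' @export
as_coefficient_tables <- function(fit, model_adopt = "adopt_fert",
                                  model_qty = "qty_fert", bounds = c(0, Inf)) {
  stopifnot(inherits(fit, "double_hurdle"))
  ci <- stats::confint(fit, level = fit$conf_level)
  fix_names <- function(v) {
    names(v) <- sub("\\(Intercept\\)", "intercept", names(v)); v
  }
  tab <- function(fitted, cim, model, link, bounds) {
    est <- fix_names(stats::coef(fitted))
    coefficient_table(model, est,
                      ci_lo = pmin(cim[, "lo"], est), ci_hi = pmax(cim[, "hi"], est),
                      link = link, bounds = bounds)
  }
  out <- list(
    tab(fit$adoption, ci$adoption, model_adopt, "logit", c(0, 1)),
    tab(fit$intensity, ci$intensity, model_qty,
        if (fit$link == "log") "log" else "identity", bounds)
  )
  stats::setNames(out, c(model_adopt, model_qty))
}

#' Default behavioural coefficient tables
#'
#' A complete, internally consistent set of tables for the nine sub-models,
#' with the hypothesised subsidy signs: positive on fertilizer and legume
#' adoption, negative on manure adoption. Values are plausible defaults for
#' a maize-mixed smallholder system, not fitted estimates; load fitted
#' tables with [read_coefficients()] for real studies.
#'
#' @param ci_spread half-width of the shipped confidence intervals as a
#'   fraction of `abs(estimate)` for slope coefficients (default 0.25);
#'   intercepts get a fixed additive half-width of 0.15, reflecting that
#'   survey intercepts are estimated much more precisely than effect sizes
#'   (a multiplicative interval on a log-link intercept would span an
#'   implausible outcome range).
#' @return named list of [coefficient_table]s.
#' @export
default_coefficient_tables <- function(ci_spread = 0.25) {
  mk <- function(model, est, link, bounds) {
    e <- unlist(est)
    half <- ifelse(names(e) == "intercept", 0.15, abs(e) * ci_spread)
    coefficient_table(model, e, ci_lo = e - half, ci_hi = e + half,
                      link = link, bounds = bounds)
  }
  list(
    adopt_fert = mk("adopt_fert",
      c(intercept = 0.6, subsidy_share = 1.2, livestock_tlu = 0.05,
        education = 0.03, legume_planted = 0.30, farm_type2 = 0.30,
        farm_type3 = 0.60), "logit", c(0, 1)),
    qty_fert = mk("qty_fert",
      c(intercept = 3.9, subsidy_share = 0.50, farm_type2 = 0.25,
        farm_type3 = 0.50, soil_n_100 = -0.010), "log", c(0, 400)),
    adopt_manure = mk("adopt_manure",
      c(intercept = -0.2, subsidy_share = -0.80, livestock_tlu = 0.15,
        farm_type3 = 0.50), "logit", c(0, 1)),
    qty_manure = mk("qty_manure",
      c(intercept = 6.0, livestock_tlu = 0.10, farm_type3 = 0.40),
      "log", c(0, 8000)),
    adopt_legume = mk("adopt_legume",
      c(intercept = -0.7, subsidy_share = 0.60, education = 0.04),
      "logit", c(0, 1)),
    share_legume = mk("share_legume",
      c(intercept = -1.2, education = 0.02), "logit", c(0, 0.8)),
    adopt_swc = mk("adopt_swc",
      c(intercept = -2.5, slope_pct = 0.08), "logit", c(0, 1)),
    yield_maize = mk("yield_maize",
      c(intercept = 6.7, soil_n_100 = 0.015, fert_kg_100 = 0.12,
        manure_t = 0.05, cultivation_period = -0.010, farm_type3 = 0.20,
        slope_pct = -0.005), "log", c(0, 6000)),
    yield_legume = mk("yield_legume",
      c(intercept = 6.2, soil_p_100 = 0.010, cultivation_period = -0.008),
      "log", c(0, 3000))
  )
}

#' Identity-link all-zero coefficient tables (null model)
#'
#' With every coefficient zero and identity links, every predicted amount
#' and yield is the link-inverse of zero, i.e. exactly 0; combined with
#' all-zero ecological parameters this makes soil stocks constant over any
#' horizon, a useful structural check.
#'
#' @return named list of [coefficient_table]s.
#' @export
null_model_tables <- function() {
  tabs <- lapply(MODEL_NAMES, function(m) {
    link <- if (startsWith(m, "adopt")) "logit" else "identity"
    coefficient_table(m, c(intercept = 0), link = link, bounds = c(0, Inf))
  })
  stats::setNames(tabs, MODEL_NAMES)
}

#' All-zero ecological parameter vector (null model)
#'
#' @return named numeric vector with every ecological parameter set to 0
#'   (harvest indices kept at 1 to avoid division by zero; with zero yields
#'   they never enter).
#' @export
null_eco_params <- function() {
  ec <- as_eco_params(default_eco_coefficients())
  ec[] <- 0
  ec[c("hi_maize", "hi_legume")] <- 1
  ec[["leach_clay_max"]] <- 60
  ec
}
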