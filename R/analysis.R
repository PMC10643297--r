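# Post-simulation statistics: moving averages, empirical confidence bands
# across replications, period summaries and Bonferroni-corrected pairwise
# scenario comparisons, plus a base-graphics trend plot.

#' Centred moving average with shrinking edge windows
#'
#' @param series numeric vector.
#' @param window odd window width (default 3); `1` is the identity.
#' @return smoothed vector of the same length; at the edges the window is
#'   truncated to the available values, so a constant series is a fixed
#'   point.
#' @export
#' @examples
#' moving_average(c(1, 2, 3, 4), 3) # 1.5 2 3 3.5
moving_average <- function(series, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(series)
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    mean(series[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Mean and empirical quantile bands across replications
#'
#' @param reps numeric matrix, replications in rows, years in columns (or a
#'   list of equal-length replicate series).
#' @param lo,hi band quantiles (defaults 0.05 and 0.95).
#' @return data.frame with columns `year`, `mean`, `lower`, `upper`.
#' @export
ci_bands <- function(reps, lo = 0.05, hi = 0.95) {
  if (is.list(reps)) reps <- do.call(rbind, reps)
  stopifnot(is.matrix(reps), lo <= hi)
  data.frame(
    year = seq_len(ncol(reps)),
    mean = colMeans(reps),
    lower = apply(reps, 2, stats::quantile, probs = lo, names = FALSE),
    upper = apply(reps, 2, stats::quantile, probs = hi, names = FALSE)
  )
}

#' Bonferroni-corrected pairwise scenario comparison
#'
#' Moving-averages each replicate series, runs a Welch two-sample test per
#' year between the two scenarios' replicate values, and applies a
#' Bonferroni correction, `p_adj = min(1, m * p)`, with `m` the size of the
#' simultaneous comparison family (by default the number of years; multiply
#' by the number of scenario pairs when testing a batch). The overall
#' verdict is significant if any adjusted p-value falls below `alpha`.
#'
#' @param reps_a,reps_b numeric matrices (replications x years) for the two
#'   scenarios.
#' @param alpha family-wise significance level (default 0.05).
#' @param window moving-average window (default 3).
#' @param m comparison family size (default `ncol(reps_a)`).
#' @return list: `per_year` (data.frame `year`, `p`, `p_adj`), `significant`
#'   (logical verdict), `alpha`, `m`.
#' @export
bonferroni_compare <- function(reps_a, reps_b, alpha = 0.05, window = 3,
                               m = NULL) {
  if (is.list(reps_a)) reps_a <- do.call(rbind, reps_a)
  if (is.list(reps_b)) reps_b <- do.call(rbind, reps_b)
  stopifnot(ncol(reps_a) == ncol(reps_b))
  n_years <- ncol(reps_a)
  if (is.null(m)) m <- n_years
  sm_a <- t(apply(reps_a, 1, moving_average, window = window))
  sm_b <- t(apply(reps_b, 1, moving_average, window = window))
  p <- vapply(seq_len(n_years), function(j) {
    a <- sm_a[, j]; b <- sm_b[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  p_adj <- pmin(1, m * p)
  list(per_year = data.frame(year = seq_len(n_years), p = p, p_adj = p_adj),
       significant = any(p_adj < alpha), alpha = alpha, m = m)
}

#' Median and range of per-replicate period means
#'
#' Summarises each replicate by its mean over the simulated period, then
#' reports the median and range across replicates (the box-plot companion
#' of the trend curves).
#'
#' @param reps numeric matrix (replications x years) or list of series.
#' @return list: `median`, `min`, `max`, and `period_means` per replicate.
#' @export
period_summary <- function(reps) {
  if (is.list(reps)) reps <- do.call(rbind, reps)
  means <- rowMeans(reps)
  list(median = stats::median(means), min = min(means), max = max(means),
       period_means = means)
}

#' Extract a replications-by-years matrix from simulation output
#'
#' @param output long-format data.frame from [run_experiment()].
#' @param scenario,variable,farm_type record selectors (`farm_type = "all"`
#'   for the whole population).
#' @return numeric matrix, one row per replication, one column per year.
#' @export
output_matrix <- function(output, scenario, variable, farm_type = "all") {
  sel <- output[output$scenario == scenario & output$variable == variable &
                  output$farm_type == farm_type, ]
  if (!nrow(sel)) stop("no records for scenario=", scenario,
                       " variable=", variable, " farm_type=", farm_type)
  reps <- sort(unique(sel$replication))
  years <- sort(unique(sel$year))
  mat <- matrix(NA_real_, length(reps), length(years),
                dimnames = list(reps, years))
  mat[cbind(match(sel$replication, reps), match(sel$year, years))] <- sel$value
  mat
}

#' Plot scenario trends with confidence bands
#'
#' @param output long-format simulation output.
#' @param variable variable to plot (e.g. `"fert_kg_ha"`).
#' @param farm_type farm type selector (default `"all"`).
#' @param window moving-average window applied to the plotted curves.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the list of per-scenario band data.frames.
#' @export
plot_scenario_trends <- function(output, variable, farm_type = "all",
                                 window = 3, ...) {
  scenarios <- unique(output$scenario)
  bands <- lapply(scenarios, function(sc) {
    mat <- output_matrix(output, sc, variable, farm_type)
    mat <- t(apply(mat, 1, moving_average, window = window))
    ci_bands(mat)
  })
  names(bands) <- scenarios
  ylim <- range(unlist(lapply(bands, function(b) c(b$lower, b$upper))))
  cols <- grDevices::hcl.colors(max(3, length(scenarios)), "Dark 3")
  graphics::plot(NA, xlim = range(bands[[1]]$year), ylim = ylim,
                 xlab = "year", ylab = variable, ...)
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    graphics::polygon(c(b$year, rev(b$year)), c(b$lower, rev(b$upper)),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(b$year, b$mean, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = scenarios, col = cols[seq_along(bands)],
                   lwd = 2, bty = "n")
  invisible(bands)
}
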