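# Monte Carlo synthesis of the unsampled household population and
# GIS-style proportional upscaling of plots onto the cultivated landscape.

#' Synthesize the full household population from a survey sample
#'
#' Sampled households are kept verbatim (`sampled = TRUE`). Synthetic
#' households are produced by resampling sample rows within farm type, with
#' continuous attributes jittered by a normal kernel (sd a fraction of the
#' within-type sd), so the empirical joint structure of the sample is
#' preserved without distributional assumptions. Farm-type proportions of
#' the synthetic set follow the sample's (largest-remainder rounding).
#'
#' @param sample household table (see [read_survey()] schema).
#' @param target_count desired total population size (>= sample size).
#' @param jitter_sd_frac jitter kernel sd as a fraction of the within-type
#'   attribute sd (default 0.10; 0 yields exact copies).
#' @return household table of `target_count` rows; synthetic households get
#'   ids `synth_<k>` and `sampled = FALSE`.
#' @export
synthesize_households <- function(sample, target_count, jitter_sd_frac = 0.10) {
  stopifnot(nrow(sample) > 0)
  if (target_count < nrow(sample))
    stop("target_count must be >= sample size")
  types <- sort(unique(sample$farm_type))
  if (!all(1:3 %in% types))
    stop("empty farm-type stratum in sample: type(s) ",
         paste(setdiff(1:3, types), collapse = ", "), " missing")
  n_extra <- target_count - nrow(sample)
  props <- as.numeric(table(factor(sample$farm_type, levels = types))) / nrow(sample)
  # largest-remainder allocation of the synthetic counts across types
  raw <- props * n_extra
  alloc <- floor(raw)
  rem <- n_extra - sum(alloc)
  if (rem > 0) {
    order_rem <- order(raw - alloc, decreasing = TRUE)
    alloc[order_rem[seq_len(rem)]] <- alloc[order_rem[seq_len(rem)]] + 1
  }
  cont_cols <- c("head_age", "education", "labour", "income", "livestock")
  synth <- vector("list", length(types))
  k <- 0
  for (j in seq_along(types)) {
    stratum <- sample[sample$farm_type == types[j], , drop = FALSE]
    if (nrow(stratum) == 0 && alloc[j] > 0)
      stop("empty farm-type stratum ", types[j])
    if (alloc[j] == 0) next
    rows <- stratum[base::sample.int(nrow(stratum), alloc[j], replace = TRUE), ,
                    drop = FALSE]
    for (cc in cont_cols) {
      s <- stats::sd(stratum[[cc]])
      if (is.na(s) || s == 0) next
      rows[[cc]] <- pmax(0, rows[[cc]] +
                           stats::rnorm(nrow(rows), 0, jitter_sd_frac * s))
    }
    rows$household_id <- paste0("synth_", k + seq_len(nrow(rows)))
    k <- k + nrow(rows)
    rows$sampled <- FALSE
    synth[[j]] <- rows
  }
  out <- rbind(sample, do.call(rbind, synth))
  rownames(out) <- NULL
  out
}

#' Upscale the sampled plot count to the landscape total
#'
#' @param sampled_plots number of surveyed plots.
#' @param sampled_fraction fraction of the cultivated land the sample
#'   represents, in `(0, 1]`.
#' @return total plot count, `round(sampled_plots / sampled_fraction)`.
#' @export
#' @examples
#' upscale_plot_count(451, 0.171) # 2637 plots landscape-wide
upscale_plot_count <- function(sampled_plots, sampled_fraction) {
  if (sampled_fraction <= 0 || sampled_fraction > 1)
    stop("sampled_fraction must be in (0, 1]")
  round(sampled_plots / sampled_fraction)
}

# Region-growing placement of one plot of npix pixels starting from a free
# seed pixel; returns pixel indices (column-major) or NULL if blocked.
grow_plot <- function(free, nr, nc, seed_idx, npix) {
  taken <- seed_idx
  frontier <- seed_idx
  while (length(taken) < npix) {
    r <- ((frontier - 1) %% nr) + 1
    cl <- ((frontier - 1) %/% nr) + 1
    cand <- c((frontier - 1)[r > 1], (frontier + 1)[r < nr],
              (frontier - nr)[cl > 1], (frontier + nr)[cl < nc])
    cand <- setdiff(unique(cand), taken)
    cand <- cand[free[cand]]
    if (!length(cand)) break
    need <- npix - length(taken)
    pick <- cand[seq_len(min(need, length(cand)))]
    taken <- c(taken, pick)
    frontier <- pick
  }
  taken
}

#' Place plots on the cultivated landscape
#'
#' Sampled plots retain their surveyed pixels (given in `plot_map`);
#' synthetic households receive plots whose pixel counts are resampled from
#' the sampled plot-size distribution of their farm type, placed on
#' unoccupied cultivated pixels by region growing from a random seed pixel.
#' No pixel is assigned twice. Each pixel is 10 m x 10 m = 0.01 ha.
#'
#' @param households full household table (sampled + synthetic).
#' @param sampled_plots plot table for the sampled households.
#' @param mask logical or 0/1 matrix of cultivated pixels.
#' @param plot_map integer matrix of existing plot assignments (row index
#'   into `sampled_plots`, `NA` = unassigned), or `NULL` for none.
#' @param plots_per_hh_lambda mean number of plots per synthetic household
#'   (Poisson, min 1); default matches the surveyed mean.
#' @return list: `plots` (full plot table), `plot_map` (integer matrix of
#'   plot row indices into the returned table).
#' @export
assign_plots <- function(households, sampled_plots, mask, plot_map = NULL,
                         plots_per_hh_lambda = NULL) {
  nr <- nrow(mask); nc <- ncol(mask)
  mask <- matrix(as.logical(mask), nr, nc)
  if (is.null(plot_map)) plot_map <- matrix(NA_integer_, nr, nc)
  new_hh <- households[!households$sampled, , drop = FALSE]
  hh_of_plot <- match(sampled_plots$household_id, households$household_id)
  type_of_plot <- households$farm_type[hh_of_plot]
  if (is.null(plots_per_hh_lambda))
    plots_per_hh_lambda <- nrow(sampled_plots) /
      length(unique(sampled_plots$household_id))

  free <- as.vector(mask) & is.na(as.vector(plot_map))
  out_plots <- sampled_plots
  out_map <- plot_map
  next_row <- nrow(sampled_plots)
  for (h in seq_len(nrow(new_hh))) {
    n_plots <- max(1, stats::rpois(1, plots_per_hh_lambda))
    donor_pool <- which(type_of_plot == new_hh$farm_type[h])
    if (!length(donor_pool)) donor_pool <- seq_len(nrow(sampled_plots))
    for (p in seq_len(n_plots)) {
      donor <- sampled_plots[base::sample(donor_pool, 1), , drop = FALSE]
      npix <- max(1L, as.integer(round(donor$area_ha / 0.01)))
      avail <- which(free)
      if (!length(avail))
        stop("cultivated mask exhausted: ", (nrow(new_hh) - h + 1),
             " household(s) could not be placed")
      seed_idx <- avail[base::sample.int(length(avail), 1)]
      px <- grow_plot(free, nr, nc, seed_idx, npix)
      free[px] <- FALSE
      next_row <- next_row + 1L
      row <- donor
      row$plot_id <- paste0("synth_p", next_row)
      row$household_id <- new_hh$household_id[h]
      row$row <- ((px[1] - 1) %% nr) + 1
      row$col <- ((px[1] - 1) %/% nr) + 1
      row$npix <- length(px)
      row$area_ha <- length(px) * 0.01
      out_plots <- rbind(out_plots, row)
      out_map[px] <- next_row
    }
  }
  rownames(out_plots) <- NULL
  list(plots = out_plots, plot_map = out_map)
}
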