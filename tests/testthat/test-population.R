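# Population synthesis and plot upscaling / placement.

sample_households <- function(n = 30, seed = 13) {
  set.seed(seed)
  land <- gen_landscape(40, 40, seed = seed)
  gen_survey(land, n_households = n, seed = seed + 1)
}

test_that("household synthesis keeps the sample verbatim and matches type shares", {
  sv <- sample_households()
  hh <- sv$households
  expect_identical(synthesize_households(hh, nrow(hh)), hh)

  set.seed(1)
  copies <- synthesize_households(hh, nrow(hh) + 10, jitter_sd_frac = 0)
  synth <- copies[!copies$sampled, ]
  # zero jitter: every synthetic row equals some sample row attribute-wise
  key <- function(d) paste(d$farm_type, d$head_age, d$education, d$income)
  expect_true(all(key(synth) %in% key(hh)))

  for (seed in 1:5) {
    set.seed(seed)
    pop <- synthesize_households(hh, 4 * nrow(hh))
    expect_true(all(pop$household_id[seq_len(nrow(hh))] == hh$household_id))
    for (ft in 1:3) {
      expected <- sum(hh$farm_type == ft) / nrow(hh) * (3 * nrow(hh))
      got <- sum(pop$farm_type[!pop$sampled] == ft)
      expect_lte(abs(got - expected), 1)
    }
  }
  expect_error(synthesize_households(hh[hh$farm_type != 2, ], 100),
               "stratum")
  expect_error(synthesize_households(hh, 10), ">= sample size")
})

test_that("plot upscaling divides by the sampled land fraction", {
  expect_equal(upscale_plot_count(451, 1), 451)
  expect_equal(upscale_plot_count(451, 0.171), 2637)
  expect_error(upscale_plot_count(451, 0), "\\(0, 1\\]")
})

test_that("plot placement is exclusive, on-mask, and preserves surveyed plots", {
  set.seed(17)
  land <- gen_landscape(80, 80, seed = 17)
  sv <- gen_survey(land, n_households = 20, seed = 18)
  set.seed(2)
  pop <- synthesize_households(sv$households, 2 * nrow(sv$households))
  placed <- assign_plots(pop, sv$plots, land$mask, plot_map = sv$plot_map)

  pm <- placed$plot_map
  expect_true(all(!is.na(pm[!land$mask]) == FALSE)) # nothing off-mask
  # sampled plots keep their surveyed pixels
  expect_identical(pm[!is.na(sv$plot_map)], sv$plot_map[!is.na(sv$plot_map)])
  # every assigned pixel belongs to exactly one plot (matrix is single-valued
  # by construction); counts match plot sizes
  tab <- table(pm)
  expect_equal(as.integer(tab[as.character(seq_len(nrow(placed$plots)))]),
               placed$plots$npix)
  expect_equal(placed$plots$area_ha, placed$plots$npix * 0.01)

  # per-type mean plot size close to the sample's over a few seeds
  ratios <- c()
  for (seed in 1:3) {
    set.seed(seed)
    placed_i <- assign_plots(pop, sv$plots, land$mask, plot_map = sv$plot_map)
    new_pl <- placed_i$plots[grepl("^synth_p", placed_i$plots$plot_id), ]
    ratios <- c(ratios, mean(new_pl$area_ha) / mean(sv$plots$area_ha))
  }
  expect_lt(abs(mean(ratios) - 1), 0.15)

  tiny_mask <- matrix(FALSE, 80, 80)
  tiny_mask[1:2, 1:2] <- TRUE
  expect_error(assign_plots(pop, sv$plots, tiny_mask), "exhausted")
})
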