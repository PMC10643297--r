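# Double-hurdle decisions, CI-bounded coefficient draws, bounded yield
# prediction, winsorisation/drift adjustment and hurdle estimation.

toy_hh <- function(n = 1, farm_type = 2) {
  data.frame(household_id = paste0("h", seq_len(n)), farm_type = farm_type,
             head_age = 45, head_gender = "male", education = 6, labour = 2.5,
             income = 400000, livestock = 1.5, group_membership = TRUE,
             transport_access = FALSE, communication_access = TRUE,
             sampled = TRUE)
}

toy_plots <- function(n = 1, hh = "h1") {
  data.frame(plot_id = paste0("p", seq_len(n)), household_id = hh, row = 1,
             col = seq_len(n), npix = 30, area_ha = 0.3, slope = 8, clay = 25,
             tpi = 2, cultivation_period = 8, swc_flag = FALSE,
             maize_frac = 0.8, legume_frac = 0.1, fallow_frac = 0.1,
             residue_retained_fraction = 0.5, stock_n = 1000, stock_p = 300,
             stock_k = 800, stock_soc = 20000)
}

test_that("coefficient draws honour their confidence intervals", {
  tab <- coefficient_table("qty_fert",
                           c(intercept = 4, subsidy_share = 0.5),
                           ci_lo = c(3.8, 0.3), ci_hi = c(4.2, 0.7),
                           link = "log", bounds = c(0, 400))
  degenerate <- coefficient_table("qty_fert", c(intercept = 4), link = "log")
  expect_identical(draw_coefficients(degenerate), c(intercept = 4))

  set.seed(5)
  draws <- t(replicate(10000, draw_coefficients(tab)))
  expect_true(all(draws[, 1] >= 3.8 & draws[, 1] <= 4.2))
  expect_true(all(draws[, 2] >= 0.3 & draws[, 2] <= 0.7))
  # empirical mean within 3 SE of the estimate (truncation is symmetric)
  sd1 <- (4.2 - 3.8) / (2 * 1.96)
  expect_lt(abs(mean(draws[, 1]) - 4), 3 * sd1 / sqrt(10000))

  unif <- replicate(2000, draw_coefficients(tab, method = "uniform"))
  expect_true(all(unif[1, ] >= 3.8 & unif[1, ] <= 4.2))
  expect_error(coefficient_table("qty_fert", c(intercept = 4),
                                 ci_lo = 4.5, ci_hi = 5), "ci_lo <= estimate")
})

test_that("the hurdle gate matches the logistic probability and amounts follow the link", {
  ctx <- build_context(toy_hh(), toy_plots(), s_t = 0.28)
  adopt0 <- coefficient_table("adopt_fert", c(intercept = 0), link = "logit",
                              bounds = c(0, 1))
  qty <- coefficient_table("qty_fert", c(intercept = log(50)), link = "log",
                           bounds = c(0, 400))
  h <- hurdle_decision(ctx, adopt0, qty)
  expect_equal(h$p, 0.5)

  never <- coefficient_table("adopt_fert", c(intercept = -30), link = "logit")
  set.seed(2)
  ctx_many <- ctx[rep(1, 10000), ]
  expect_equal(sum(hurdle_decision(ctx_many, never, qty)$adopted), 0)

  # hand toy: p = logistic(0.5 - 1*0.28 + 0.05*6); amount = exp(...) for adopters
  adopt <- coefficient_table(
    "adopt_fert", c(intercept = 0.5, subsidy_share = -1, education = 0.05),
    link = "logit")
  qty2 <- coefficient_table(
    "qty_fert", c(intercept = 3.5, subsidy_share = 1, education = 0.02),
    link = "log", bounds = c(0, 400))
  p_hand <- plogis(0.5 - 1 * 0.28 + 0.05 * 6)
  amt_hand <- exp(3.5 + 1 * 0.28 + 0.02 * 6)
  set.seed(3)
  sim <- hurdle_decision(ctx_many, adopt, qty2)
  expect_equal(sim$p[1], p_hand)
  expect_lt(abs(mean(sim$adopted) - p_hand), 3 * sqrt(p_hand * (1 - p_hand) / 1e4))
  expect_equal(unique(sim$amount[sim$adopted]), amt_hand)
  expect_equal(mean(sim$amount), mean(sim$adopted) * amt_hand)

  bad <- coefficient_table("adopt_fert", c(intercept = 0, no_such = 1))
  expect_error(hurdle_decision(ctx, bad, qty), "no_such")
})

test_that("decide_all is reproducible, ordered for linkages, and subsidy-monotone", {
  hh <- toy_hh(); pl <- toy_plots(4)
  tabs <- default_coefficient_tables()
  set.seed(11); d1 <- decide_all(hh, pl, 0.28, tabs)
  set.seed(11); d2 <- decide_all(hh, pl, 0.28, tabs)
  expect_identical(d1, d2)
  expect_named(d1, c("plot_id", "fert_kg_ha", "subsidised_share",
                     "manure_kg_ha", "legume_fraction",
                     "residue_retained_fraction", "swc_flag"))

  # adoption probability is strictly monotone in the subsidy share when the
  # subsidy coefficient is positive (fertilizer) / negative (manure)
  ctx0 <- build_context(hh, pl, 0); ctx0$legume_planted <- 0
  ctx7 <- build_context(hh, pl, 0.7); ctx7$legume_planted <- 0
  b_f <- setNames(tabs$adopt_fert$estimate, tabs$adopt_fert$predictor)
  b_m <- setNames(tabs$adopt_manure$estimate, tabs$adopt_manure$predictor)
  lp <- function(ctx, b) as.matrix(ctx[, names(b)]) %*% b
  expect_true(all(plogis(lp(ctx7, b_f)) > plogis(lp(ctx0, b_f))))
  expect_true(all(plogis(lp(ctx7, b_m)) < plogis(lp(ctx0, b_m))))

  # identity-link zero tables give zero amounts gated at p = 0.5
  set.seed(4)
  d0 <- decide_all(hh, pl, 0.28, null_model_tables())
  expect_true(all(d0$fert_kg_ha == 0 & d0$manure_kg_ha == 0 &
                    d0$legume_fraction == 0))
})

test_that("yield predictions are link-inverted and clamped to crop bounds", {
  ctx <- build_context(toy_hh(), toy_plots(), 0.28,
                       extra = list(legume_planted = 0, fert_kg_100 = 0.5,
                                    manure_t = 1))
  zero <- coefficient_table("yield_maize", c(intercept = 0),
                            link = "identity", bounds = c(0, 6000))
  expect_equal(predict_yield(ctx, zero), 0)

  big <- coefficient_table("yield_maize", c(intercept = 20), link = "log",
                           bounds = c(0, 6000))
  expect_equal(predict_yield(ctx, big), 6000)

  tab <- coefficient_table(
    "yield_maize", c(intercept = 6.5, soil_n_100 = 0.02, fert_kg_100 = 0.1,
                     cultivation_period = -0.01), link = "log",
    bounds = c(0, 6000))
  hand <- exp(6.5 + 0.02 * 10 + 0.1 * 0.5 - 0.01 * 8)
  expect_equal(predict_yield(ctx, tab), hand)
})

test_that("winsorisation clips to baseline limits and drift anchors the mean", {
  base <- c(10, 12, 14, 16, 18, 20, 22, 24, 26, 28)
  same <- winsorise_drift_adjust(base, base)
  expect_equal(as.numeric(same), base)
  expect_equal(attr(same, "drift"), 1)

  spiked <- c(base[-10], 1000)
  adj <- winsorise_drift_adjust(spiked, base, p_lo = 0.1, p_hi = 0.9)
  expect_equal(max(adj / attr(adj, "drift")), quantile(base, 0.9, type = 1,
                                                       names = FALSE))

  doubled <- winsorise_drift_adjust(2 * base, base, p_lo = 0, p_hi = 1)
  expect_equal(attr(doubled, "drift"), 0.5) # means ratio for a doubled set
})

test_that("fit_double_hurdle guards its preconditions and flags separation", {
  truth <- gen_behavioural_truth(200, seed = 9)
  expect_error(fit_double_hurdle(amount ~ subsidy_share, truth$data[1:30, ]),
               "at least 50")
  sep <- data.frame(amount = c(rep(0, 50), rep(100, 50)),
                    x = c(rep(0, 50), rep(1, 50)))
  expect_error(fit_double_hurdle(amount ~ x, sep), "separation")
})

test_that("fit_double_hurdle recovers generating coefficients within Wald CIs", {
  truth <- gen_behavioural_truth(2000, seed = 21)
  fit <- fit_double_hurdle(amount ~ subsidy_share + livestock_tlu + education,
                           truth$data)
  ci <- confint(fit)
  true_b1 <- truth$tables$adopt_fert$estimate
  true_b2 <- truth$tables$qty_fert$estimate
  covered <- c(true_b1 >= ci$adoption[, "lo"] & true_b1 <= ci$adoption[, "hi"],
               true_b2 >= ci$intensity[, "lo"] & true_b2 <= ci$intensity[, "hi"])
  expect_gte(mean(covered), 7 / 8) # allow one marginal miss in a single seed
  tabs <- as_coefficient_tables(fit)
  expect_s3_class(tabs$adopt_fert, "coefficient_table")
  expect_true("intercept" %in% tabs$qty_fert$predictor)
})
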