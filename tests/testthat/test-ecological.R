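# Transfer functions of the ecological module: deposition, decomposition,
# fixation, erosion and routing, leaching, gaseous losses, crop removal.

test_that("atmospheric deposition scales with the square root of rainfall", {
  ec <- eco_params(dep_a_n = 0.14, dep_a_p = 0.02, dep_a_k = 0.05)
  expect_equal(atmospheric_deposition(0, ec)$n, 0)
  d900 <- atmospheric_deposition(900, ec)
  expect_equal(d900$n, 4.2)
  d1800 <- atmospheric_deposition(1800, ec)
  for (nut in c("n", "p", "k"))
    expect_equal(d1800[[nut]], sqrt(2) * d900[[nut]])
  expect_equal(d900$c, 0) # IN5 carries no carbon
  expect_error(atmospheric_deposition(-10, ec), ">= 0")
})

test_that("mineralisation releases content x availability and decays SOM", {
  s0 <- soil_stock(0, 0, 0, 0)
  zero <- mineralisation(0, 0, s0, eco_params())
  expect_true(all(c(zero$flow$n, zero$flow$p, zero$flow$k, zero$flow$c) == 0))
  expect_equal(zero$soc_loss_c, 0)

  ec <- eco_params(manure_n = 0.012, avail_n = 0.5, k_soc = 0.03)
  m <- mineralisation(1000, 0, s0, ec)
  expect_equal(m$flow$n, 6) # 1000 x 1.2% x 0.5

  s <- soil_stock(10, 10, 10, 20000)
  expect_equal(mineralisation(0, 0, s, ec)$soc_loss_c, 600)
})

test_that("biological N fixation is ndfa x biomass x N content, N only", {
  ec <- eco_params(ndfa = 0.6, legume_n = 0.025)
  expect_equal(biological_n_fixation(0, ec)$n, 0)
  fix <- biological_n_fixation(2000, ec)
  expect_equal(fix$n, 30)
  expect_equal(fix$p + fix$k + fix$c, 0)
  expect_equal(biological_n_fixation(5000, eco_params(ndfa = 0))$n, 0)
})

test_that("erosion is multiplicative, non-decreasing in slope, halved by SWC at P=0.5", {
  ec <- eco_params(rusle_r_per_mm = 0.5, rusle_k = 0.02, rusle_c_cover = 0.3,
                   p_swc = 0.5)
  flat <- data.frame(slope = 0, swc_flag = FALSE)
  expect_gte(soil_erosion(flat, ec, 900), 0)

  slopes <- data.frame(slope = c(0, 2, 5, 10, 20, 40), swc_flag = FALSE)
  loss <- soil_erosion(slopes, ec, 900)
  expect_true(all(diff(loss) > 0))

  pair <- data.frame(slope = c(8, 8), swc_flag = c(TRUE, FALSE))
  lp <- soil_erosion(pair, ec, 900)
  expect_equal(lp[1], 0.5 * lp[2])

  # hand-multiplied: R=450, K=0.02, LS(8%), C=0.3, P=1
  ls8 <- 0.065 + 0.0456 * 8 + 0.006541 * 64
  expect_equal(soil_erosion(data.frame(slope = 8, swc_flag = FALSE), ec, 900),
               450 * 0.02 * ls8 * 0.3)
  expect_error(soil_erosion(data.frame(slope = -1, swc_flag = FALSE), ec, 900),
               ">= 0")
})

test_that("eroded sediment strips nutrients at enriched bulk concentration", {
  s <- soil_stock(1300, 390, 650, 13000, rho = 1.3, cf = 0, depth = 0.10)
  ec <- eco_params(er_n = 2, er_p = 2, er_k = 1.5, er_c = 2)
  expect_equal(erosion_nutrient_loss(0, s, ec)$n, 0)

  # ER = 1: removing the whole fine-earth layer mass removes the whole pool
  ec1 <- eco_params(er_n = 1, er_p = 1, er_k = 1, er_c = 1)
  layer_t_ha <- 1.3 * 0.10 * 1e4 # t/ha of fine earth in the layer
  total <- erosion_nutrient_loss(layer_t_ha, s, ec1)
  expect_equal(total$n, s$n)
  expect_equal(total$c, s$soc)

  # hand case: 5 t/ha x 1000 mg/kg x ER 2 x 1e-3 = 10 kg/ha
  s2 <- soil_stock(concentration_to_stock(1000, 1.3), 1, 1, 1, rho = 1.3)
  expect_equal(erosion_nutrient_loss(5, s2, ec)$n, 10)
})

test_that("sediment routing deposits d x upslope load and respects the budget", {
  ec <- c(sdr = 0.3)
  # 1x3 west-sloping strip: cell 3 -> 2 -> 1
  elev <- matrix(c(1, 2, 3), 1, 3)
  routing <- flow_routing(elev)
  expect_equal(routing, c(NA, 1L, 2L))
  nut0 <- list(n = rep(0, 3), p = rep(0, 3), k = rep(0, 3), c = rep(0, 3))

  none <- sediment_deposition(c(0, 0, 0), nut0, routing, ec)
  expect_true(all(none$soil == 0))

  donor <- sediment_deposition(c(0, 0, 10), nut0, routing, ec)
  expect_equal(donor$soil, c(0, 3, 0))

  nut2 <- list(n = c(0, 0), p = c(0, 0), k = c(0, 0), c = c(0, 0))
  expect_error(sediment_deposition(c(1, 1), nut2, c(2L, 1L), ec), "cyclic")

  set.seed(31)
  for (i in 1:10) {
    el <- matrix(cumsum(runif(25)), 5, 5)[sample(5), sample(5)]
    r <- flow_routing(el)
    loss <- runif(25, 0, 5)
    dep <- sediment_deposition(loss, list(n = loss, p = loss, k = loss,
                                          c = loss), r, ec)
    expect_lte(sum(dep$soil), sum(loss))
    expect_lte(sum(dep$flow$n), sum(loss))
  }
})

test_that("leaching fraction rises with rain, falls with clay, and is clamped", {
  s <- soil_stock(1000, 1, 500, 1)
  ec <- eco_params(leach_rate = 0.25, leach_clay_max = 60,
                   mineral_n_frac = 0.02, mineral_k_frac = 0.02)
  expect_equal(leaching_loss(0, 20, s, 50, ec)$n, 0)

  extreme <- leaching_loss(1e6, 0, s, 50, ec)
  expect_equal(extreme$n, 0.02 * 1000 + 50) # f clamped at 1

  # hand case: f = 0.25 x 0.9 x (1 - 20/60) = 0.15
  hand <- leaching_loss(900, 20, s, 50, ec)
  expect_equal(hand$n, 0.15 * (0.02 * 1000 + 50))
  expect_equal(hand$k, 0.15 * (0.02 * 500))
  expect_equal(hand$p, 0) # OUT4 carries N and K only

  rains <- vapply(c(0, 300, 600, 900, 1200),
                  function(r) leaching_loss(r, 20, s, 50, ec)$n, numeric(1))
  expect_true(all(diff(rains) >= 0))
  clays <- vapply(c(0, 15, 30, 45, 60),
                  function(cl) leaching_loss(900, cl, s, 50, ec)$n, numeric(1))
  expect_true(all(diff(clays) <= 0))
})

test_that("gaseous N loss is a bounded fraction of current mineral N", {
  ec <- eco_params(gas_base = 0.05, gas_rain = 0.10)
  expect_equal(gaseous_loss(0, 900, 0, ec)$n, 0)
  # g = 0.05 + 0.10 x 0.9 = 0.14
  expect_equal(gaseous_loss(60, 900, 10, ec)$n, 0.14 * 70)
  expect_equal(gaseous_loss(60, 900, 10, ec, soc_loss_c = 600)$c, 600)
  huge <- gaseous_loss(100, 1e6, 0, eco_params(gas_base = 0.5, gas_rain = 1))
  expect_equal(huge$n, 100) # fraction clamped at 1
})

test_that("crop removal splits grain offtake and residue export by HI", {
  ec <- eco_params(hi_maize = 0.45, grain_n_maize = 0.016,
                   residue_n = 0.007)
  zero <- crop_removal(0, 0, 0.5, ec)
  expect_equal(zero$out1$n + zero$out2$n, 0)

  all_kept <- crop_removal(2000, 0, 1, ec)
  expect_equal(all_kept$out2$n, 0)
  expect_equal(all_kept$residue_retained_kg_ha, 2000 * (1 / 0.45 - 1))

  # hand case, half the residue removed
  half <- crop_removal(2000, 0, 0.5, ec)
  res_biomass <- 2000 * (1 / 0.45 - 1)
  expect_equal(half$out1$n, 2000 * 0.016)
  expect_equal(half$out2$n, res_biomass * 0.007 * 0.5)
  expect_error(crop_removal(100, 0, 1.2, ec), "\\[0, 1\\]")
})

test_that("with all-zero coefficients every environmental flow vanishes", {
  ec <- null_eco_params()
  s <- soil_stock(1000, 300, 800, 20000)
  expect_equal(atmospheric_deposition(900, ec)$n, 0)
  m <- mineralisation(0, 0, s, ec)
  expect_equal(m$flow$c + m$soc_loss_c, 0)
  expect_equal(soil_erosion(data.frame(slope = 30, swc_flag = FALSE), ec, 900),
               0)
  expect_equal(leaching_loss(900, 10, s, 0, ec)$n, 0)
  expect_equal(gaseous_loss(0, 900, 0, ec)$n, 0)
})
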