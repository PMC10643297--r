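# Stock/concentration conversions, flow-vector masks, mass-balance update
# and fertilizer-product conversion.

test_that("concentration/stock conversion matches the layer-mass formula and inverts", {
  expect_equal(concentration_to_stock(0, 1.3, 0, 0.10), 0)
  expect_equal(concentration_to_stock(100, 1.3, 0, 0.10), 130)
  # coarse fragments reduce the fine-earth mass
  expect_equal(concentration_to_stock(100, 1.3, 0.5, 0.10), 65)

  set.seed(42)
  x <- runif(1000, 0, 5000)
  rho <- runif(1000, 0.9, 1.8)
  cf <- runif(1000, 0, 0.6)
  depth <- runif(1000, 0.05, 0.3)
  expect_equal(
    stock_to_concentration(concentration_to_stock(x, rho, cf, depth),
                           rho, cf, depth),
    x)
  expect_error(concentration_to_stock(-1, 1.3), ">= 0")
})

test_that("flow vectors enforce the pathway-nutrient masks", {
  expect_silent(flow_vector("IN1", n = 10, p = 5))
  expect_error(flow_vector("IN1", k = 1), "does not carry K")
  expect_error(flow_vector("IN3", p = 1), "does not carry P")
  expect_error(flow_vector("OUT4", p = 2), "does not carry P")
  expect_error(flow_vector("OUT5", k = 2), "does not carry K")
  expect_error(flow_vector("IN2", n = -1), ">= 0")
  # every declared mask is a subset of the four tracked nutrients
  expect_true(all(unlist(PATHWAY_NUTRIENTS) %in% c("n", "p", "k", "c")))
})

test_that("annual stock update is an exact ledger with floor-and-log clipping", {
  s <- soil_stock(900, 300, 800, 20000)
  bal <- update_soil_stock(
    s, list(flow_vector("IN5", n = 10, p = 2, k = 3)),
    list(flow_vector("OUT1", n = 10, p = 2, k = 3)))
  expect_equal(bal$stock$n, 900)
  expect_equal(bal$stock$soc, 20000)
  expect_true(all(unlist(bal$clipped) == 0))

  upd <- update_soil_stock(
    s, list(flow_vector("IN1", n = 60)), list(flow_vector("OUT4", n = 75)))
  expect_equal(upd$stock$n, 885)

  low <- soil_stock(5, 5, 5, 5)
  floored <- update_soil_stock(low, list(),
                               list(flow_vector("OUT4", n = 20)))
  expect_equal(floored$stock$n, 0)
  expect_equal(floored$clipped$n, 15)

  expect_error(update_soil_stock(s, list(flow_vector("OUT1", n = 1)), list()),
               "not allowed")
})

test_that("mass conservation holds exactly for random flow sets", {
  set.seed(7)
  for (i in 1:25) {
    s <- soil_stock(runif(4, 0, 50), runif(4, 0, 50), runif(4, 0, 50),
                    runif(4, 0, 500))
    ins <- list(flow_vector("IN2", n = runif(4, 0, 40), p = runif(4, 0, 40),
                            k = runif(4, 0, 40), c = runif(4, 0, 40)),
                flow_vector("IN5", n = runif(4, 0, 10), p = runif(4, 0, 10),
                            k = runif(4, 0, 10)))
    outs <- list(flow_vector("OUT3", n = runif(4, 0, 60), p = runif(4, 0, 60),
                             k = runif(4, 0, 60), c = runif(4, 0, 600)))
    upd <- update_soil_stock(s, ins, outs)
    for (pool in c("n", "p", "k", "soc")) {
      nut <- if (pool == "soc") "c" else pool
      lhs <- upd$stock[[pool]] - s[[pool]] - upd$clipped[[pool]]
      rhs <- Reduce(`+`, lapply(ins, `[[`, nut)) -
        Reduce(`+`, lapply(outs, `[[`, nut))
      expect_lt(max(abs(lhs - rhs)), 1e-9)
      expect_true(all(upd$stock[[pool]] >= 0))
    }
  }
})

test_that("fertilizer products convert to elemental IN1 nutrients", {
  zero <- product_to_nutrients(0, "urea")
  expect_equal(zero$n, 0)
  expect_equal(zero$p, 0)

  urea <- product_to_nutrients(175, "urea")
  expect_equal(urea$n, 80.5)

  dap <- product_to_nutrients(87, "dap")
  expect_equal(attr(dap, "p2o5"), 40.02)
  expect_equal(dap$p, 40.02 * P2O5_TO_P)
  expect_equal(dap$n, 87 * 0.18)

  expect_error(product_to_nutrients(10, "guano"), "known grades.*urea")
  expect_error(product_to_nutrients(-1, "urea"), ">= 0")
  mop <- list(name = "mop", n_frac = 0, p2o5_frac = 0, k2o_frac = 0.6)
  expect_error(product_to_nutrients(10, mop), "N and P only")
})
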