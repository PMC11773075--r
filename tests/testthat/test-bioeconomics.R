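# Static reference points and rent accounting against the published
# benchmark rows and against brute-force oracles.

test_that("price and cost back-derivation inverts the revenue/cost identities", {
  expect_rel_equal(rk$econ$price, 9599.6, 1e-3)
  expect_rel_equal(rk$econ$unit_cost, 8611.9, 1e-3)
  expect_rel_equal(sc_fish$econ$price, 1481.3, 1e-3)
  expect_rel_equal(sc_fish$econ$unit_cost, 1185.6, 1e-3)
  # round trip: a point built from known (p, c) returns them exactly
  p <- 1234.5; cc <- 678.9
  ref <- reference_point("MSY", effort = 400, harvest = 900, biomass = 1e4,
                         total_revenue = p * 900, total_cost = cc * 400)
  ec <- derive_price_cost(ref)
  expect_equal(ec$price, p)
  expect_equal(ec$unit_cost, cc)
  expect_error(derive_price_cost(reference_point("MSY", 0, 0, 1, 0, 0)),
               class = "gs_domain_error")
})

test_that("MSY point matches the closed forms and the published row", {
  pt <- msy_point(rk$bio, rk$econ)
  expect_rel_equal(pt$effort, 5982, 1e-3)
  expect_rel_equal(pt$harvest, 10662.65, 1e-3)
  expect_equal(pt$biomass, 81872.75)
  expect_equal(pt$rent, pt$total_revenue - pt$total_cost)
  # degenerate growth: no sustainable fishery
  pt0 <- msy_point(biological_params(1e4, 1e-5, 0), rk$econ)
  expect_equal(c(pt0$effort, pt0$harvest), c(0, 0))
  expect_equal(pt0$biomass, 5e3)
  # harvest agrees with grid maximisation of the yield parabola
  gm <- grid_argmax(function(e) equilibrium_yield(e, rk$bio), 0,
                    rk$bio$r / rk$bio$q)
  expect_rel_equal(pt$harvest, gm$y, 1e-6)
})

test_that("MEY point maximises rent and matches the published row", {
  pt <- mey_point(rk$bio, rk$econ)
  expect_rel_equal(pt$effort, 4476.32, 5e-3)
  expect_rel_equal(pt$harvest, 9987.41, 5e-3)
  expect_rel_equal(pt$rent, 57323108, 5e-3)
  # rent at MEY beats every effort on a fine grid
  gm <- grid_argmax(function(e)
    rk$econ$price * equilibrium_yield(e, rk$bio) - rk$econ$unit_cost * e,
    0, rk$bio$r / rk$bio$q)
  expect_gte(pt$rent, gm$y - 1e-6 * abs(gm$y))
  expect_lt(abs(pt$effort - gm$x), 2 * gm$step)
  # costless limit collapses MEY onto MSY except for the stock level
  free <- economic_params(rk$econ$price, 0)
  expect_equal(mey_point(rk$bio, free)$effort, msy_point(rk$bio, free)$effort)
  expect_equal(mey_point(rk$bio, free)$harvest, msy_point(rk$bio, free)$harvest)
  expect_equal(mey_point(rk$bio, free)$biomass, rk$bio$K / 2)
})

test_that("open-access equilibrium dissipates rent at the published effort and harvest", {
  pt <- oae_point(rk$bio, rk$econ)
  expect_rel_equal(pt$effort, 8952.63, 5e-3)
  expect_rel_equal(pt$harvest, 8032.04, 5e-3)
  expect_identical(pt$rent, 0)
  expect_equal(pt$biomass,
               rk$econ$unit_cost / (rk$econ$price * rk$bio$q))
  expect_rel_equal(oae_point(ta$bio, ta$econ)$harvest, 3351.58, 5e-3)
  # costless open access drives effort to r/q and yield to zero
  free <- economic_params(rk$econ$price, 0)
  pt0 <- oae_point(rk$bio, free)
  expect_equal(pt0$effort, rk$bio$r / rk$bio$q)
  expect_equal(pt0$harvest, 0)
  expect_equal(pt0$biomass, 0)
})

test_that("a never-profitable fishery returns structured infeasibility", {
  dear <- economic_params(price = 1, unit_cost = 1e9)
  expect_gte(cost_price_ratio(rk$bio, dear), 1)
  expect_false(mey_point(rk$bio, dear)$feasible)
  expect_equal(mey_point(rk$bio, dear)$effort, 0)
  expect_false(oae_point(rk$bio, dear)$feasible)
  expect_equal(oae_point(rk$bio, dear)$effort, 0)
})

test_that("algebraic identities link the regimes across random parameter draws", {
  set.seed(13)
  for (i in 1:200) {
    f <- random_fishery()
    mey <- mey_point(f$bio, f$econ)
    oae <- oae_point(f$bio, f$econ)
    msyp <- msy_point(f$bio, f$econ)
    expect_equal(oae$effort, 2 * mey$effort, tolerance = 1e-9)
    expect_equal(oae$biomass, 2 * mey$biomass - f$bio$K, tolerance = 1e-6)
    expect_gte(mey$rent, msyp$rent - 1e-6 * abs(msyp$rent))
    expect_true(all(c(mey$harvest, oae$harvest) >= 0))
    expect_lte(mey$harvest, msyp$harvest * (1 + 1e-12))
    expect_lte(oae$harvest, msyp$harvest * (1 + 1e-12))
  }
})

test_that("raising the unit cost lowers effort and raises equilibrium stock", {
  costs <- seq(1000, 30000, by = 1000)
  pts_mey <- lapply(costs, function(cc)
    mey_point(rk$bio, economic_params(rk$econ$price, cc)))
  pts_oae <- lapply(costs, function(cc)
    oae_point(rk$bio, economic_params(rk$econ$price, cc)))
  expect_true(all(diff(sapply(pts_mey, `[[`, "effort")) <= 0))
  expect_true(all(diff(sapply(pts_oae, `[[`, "effort")) <= 0))
  expect_true(all(diff(sapply(pts_mey, `[[`, "biomass")) >= 0))
  expect_true(all(diff(sapply(pts_oae, `[[`, "biomass")) >= 0))
})

test_that("sustainable economics at chosen efforts matches the regime points", {
  e_oae <- oae_point(rk$bio, rk$econ)$effort
  eco <- economics_at_effort(c(0, 4476.32, e_oae), rk$bio, rk$econ)
  expect_equal(eco$rent[1], 0)
  expect_rel_equal(eco$rent[2], 57323108, 5e-3)
  expect_lt(abs(eco$rent[3]), 1e-6 * eco$total_revenue[3])
  expect_warning(economics_at_effort(2 * rk$bio$r / rk$bio$q, rk$bio, rk$econ),
                 "beyond r/q")
})

test_that("the reference table reproduces the published rows for all four fisheries", {
  published <- list(
    R_kanagurta = list(MSY = c(5982, 10662.65), MEY = c(4476.32, 9987.41),
                       OAE = c(8952.63, 8032.04)),
    T_albacares = list(MSY = c(6614, 12991.16), MEY = c(6155.46, 12928.77),
                       OAE = c(12310.92, 3351.58)),
    S_commerson = list(MSY = c(2222, 2574.83), MEY = c(1454.68, 2267.75),
                       OAE = c(2909.37, 2328.47)),
    S_longiceps = list(MSY = c(6913, 135857.80), MEY = c(6553.21, 135490.31),
                       OAE = c(13106.43, 26793.52)))
  for (nm in names(published)) {
    b <- benchmarks[[nm]]
    tab <- reference_table(b$bio, b$econ, species = b$species)
    for (rg in names(published[[nm]])) {
      row <- tab[tab$regime == rg, ]
      expect_rel_equal(row$effort_boats, published[[nm]][[rg]][1], 5e-3)
      expect_rel_equal(row$harvest_t, published[[nm]][[rg]][2], 5e-3)
    }
    expect_equal(tab$profit_omr[tab$regime == "OAE"], 0)
  }
})
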