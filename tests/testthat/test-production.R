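# Schaefer core mathematics: logistic growth, harvest, yield parabola,
# CPUE line and its inversion.

test_that("logistic growth vanishes at the origin and at carrying capacity, peaks at MSY", {
  bio <- rk$bio
  expect_equal(growth_increment(0, bio), 0)
  expect_equal(growth_increment(bio$K, bio), 0)
  # peak growth at K/2 equals rK/4, the published MSY for this stock
  expect_rel_equal(growth_increment(bio$K / 2, bio), 10662.65, 1e-4)
  expect_error(growth_increment(-1, bio), class = "gs_domain_error")
  # concavity: grid maximum lands at K/2 within one grid step
  gm <- grid_argmax(function(x) growth_increment(x, bio), 0, bio$K, n = 4001)
  expect_lt(abs(gm$x - bio$K / 2), 2 * gm$step)
})

test_that("catch rate is bilinear in effort and biomass", {
  expect_equal(catch_rate(0, 5e4, rk$bio), 0)
  expect_rel_equal(catch_rate(5982, 81872.75, 2.177e-5), 10662.5, 1e-3)
  x <- catch_rate(1234, 5e4, rk$bio)
  expect_equal(catch_rate(2468, 5e4, rk$bio), 2 * x)
  expect_equal(catch_rate(1234, 1e5, rk$bio), 2 * x)
  expect_error(catch_rate(-1, 1, rk$bio), class = "gs_domain_error")
})

test_that("annual biomass step follows the difference equation and floors collapse", {
  bio <- rk$bio
  s <- step_biomass(biomass_state(2000, bio$K), 500, bio)
  expect_equal(s$biomass, bio$K - 500)
  expect_equal(s$year, 2001L)
  # replacement: harvesting rK/4 at K/2 holds the stock still
  s <- step_biomass(biomass_state(2000, bio$K / 2), msy(bio), bio)
  expect_equal(s$biomass, bio$K / 2)
  # over-harvest clamps at the floor and flags collapse
  s <- step_biomass(biomass_state(2000, 1000), 5000, bio)
  expect_true(s$collapsed)
  expect_equal(s$biomass, 1e-6 * bio$K)
  expect_error(step_biomass(biomass_state(2000, 1000), -1, bio),
               class = "gs_domain_error")
})

test_that("constant MSY-level effort drives the stock from K to K/2", {
  bio <- rk$bio
  e_msy <- bio$r / (2 * bio$q)
  st <- biomass_state(0, bio$K)
  for (i in 1:500) st <- step_biomass(st, catch_rate(e_msy, st$biomass, bio), bio)
  expect_rel_equal(st$biomass, bio$K / 2, 1e-3)
})

test_that("unfished stock converges monotonically to K when r < 1", {
  set.seed(42)
  for (i in 1:20) {
    K <- runif(1, 1e3, 1e6)
    bio <- biological_params(K, 1e-5, runif(1, 0.05, 0.99))
    st <- biomass_state(0, runif(1, 0.01, 0.99) * K)
    prev <- st$biomass
    for (j in 1:300) {
      st <- step_biomass(st, 0, bio)
      expect_gte(st$biomass, prev)
      prev <- st$biomass
    }
    expect_rel_equal(st$biomass, K, 1e-3)
  }
})

test_that("equilibrium yield parabola has roots at 0 and r/q and peak rK/4 at r/(2q)", {
  bio <- rk$bio
  expect_equal(equilibrium_yield(0, bio), 0)
  expect_equal(equilibrium_yield(bio$r / bio$q, bio), 0, tolerance = 1e-9)
  expect_rel_equal(equilibrium_yield(5982, bio), 10662.6, 1e-3)
  # raw parabola goes negative beyond r/q (deliberately unclamped)
  expect_lt(equilibrium_yield(1.1 * bio$r / bio$q, bio), 0)
  expect_error(equilibrium_yield(1, biological_params(1e4, 1e-5, 0)),
               class = "gs_domain_error")
  # grid oracle: maximiser at r/(2q), maximum rK/4
  gm <- grid_argmax(function(e) equilibrium_yield(e, bio), 0, bio$r / bio$q)
  expect_lt(abs(gm$x - bio$r / (2 * bio$q)), 2 * gm$step)
  expect_rel_equal(gm$y, msy(bio), 1e-6)
})

test_that("CPUE line evaluates, matches yield/effort, and inverts to (K, r)", {
  bio <- rk$bio
  line <- cpue_line_from_params(bio)
  expect_equal(cpue_from_effort(0, line), line$a)
  expect_equal(cpue_from_effort(-line$a / line$b, line), 0)
  # H(E) = E * CPUE(E) identity along the model line
  for (e in c(100, 2500, 5982, 9000)) {
    expect_equal(equilibrium_yield(e, bio), e * cpue_from_effort(e, line),
                 tolerance = 1e-10)
  }
  rec <- params_from_cpue_line(line, bio$q)
  expect_equal(rec$K, bio$K, tolerance = 1e-12)
  expect_equal(rec$r, bio$r, tolerance = 1e-12)
})

test_that("forward-then-inverse CPUE line is the identity over random parameters", {
  set.seed(7)
  for (i in 1:1000) {
    K <- exp(runif(1, log(1e3), log(1e7)))
    q <- exp(runif(1, log(1e-7), log(1e-3)))
    r <- runif(1, 0.02, 2)
    bio <- biological_params(K, q, r)
    rec <- params_from_cpue_line(cpue_line_from_params(bio), q)
    expect_equal(rec$K, K, tolerance = 1e-9)
    expect_equal(rec$r, r, tolerance = 1e-9)
  }
})

test_that("degenerate CPUE lines are rejected", {
  expect_error(params_from_cpue_line(cpue_line(3.5, 0.001), 1e-5),
               class = "gs_estimation_error")
  expect_error(params_from_cpue_line(cpue_line(-1, -0.001), 1e-5),
               class = "gs_estimation_error")
  expect_error(params_from_cpue_line(cpue_line(1, -1), -1),
               class = "gs_domain_error")
  # a = 1, b = -1, q = 1 -> K = 1, r = 1
  p <- params_from_cpue_line(cpue_line(1, -1), 1)
  expect_equal(c(p$K, p$r), c(1, 1))
})
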