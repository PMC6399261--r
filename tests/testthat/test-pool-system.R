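test_that("constructor rejects ill-formed systems", {
  A0 <- matrix(0, 2, 2)
  expect_error(pool_system(c("a", "b"), c("vegetation", "soil"), c(TRUE, FALSE),
                           b = c(0.5, 0.2), A = A0, K = c(1, 1)),
               "sum to 1")
  expect_error(pool_system(c("a", "b"), c("vegetation", "soil"), c(TRUE, FALSE),
                           b = c(0.5, 0.5), A = A0, K = c(1, 1)),
               "vegetation pools")
  Abad <- matrix(c(0, 0.6, 0.6, 0), 2, 2)
  expect_error(pool_system(c("a", "b"), c("vegetation", "soil"),
                           c(TRUE, FALSE), b = c(1, 0), A = Abad, K = c(1, 1)),
               "not receive transfers")
  expect_error(pool_system("a", "vegetation", TRUE, 1, matrix(0, 1, 1), K = 0),
               "strictly positive")
  expect_error(pool_system("a", "vegetation", TRUE, 1, matrix(0.2, 1, 1), 0.5),
               "self-transfers")
  Abig <- matrix(0, 2, 2); Abig[2, 1] <- 1.2
  expect_error(pool_system(c("a", "b"), c("vegetation", "soil"),
                           c(TRUE, FALSE), b = c(1, 0), A = Abig, K = c(1, 1)),
               "exceed 1")
})

test_that("steady state solves the per-pool balance", {
  expect_equal(drop(steady_state(one_pool(0.5), u0 = 2)), c(biomass = 4))
  # two-pool chain: closed-form solve of the 2x2 balance equations
  expect_equal(drop(steady_state(two_pool_chain(), u0 = 1)),
               c(veg = 1, soil = 2))
  expect_equal(drop(steady_state(two_pool_chain(), u0 = 0)),
               c(veg = 0, soil = 0))
  # per-cell influx scales each cell's solution
  X <- steady_state(two_pool_chain(), u0 = c(1, 3))
  expect_equal(X[2, ], 3 * X[1, ])
  expect_error(steady_state(one_pool(), u0 = 1, xi0 = 0), "strictly positive")
  expect_error(steady_state(one_pool(), u0 = -1), "non-negative")
})

test_that("steady state is a fixed point of the annual step", {
  for (seed in 1:5) {
    sys <- random_system(sample(2:5, 1), seed)
    n <- 7
    set.seed(seed + 100)
    u0 <- runif(n, 10, 800)
    xi0 <- matrix(runif(n * length(sys$K), 0.5, 1.2), n)
    X <- steady_state(sys, u0, xi0)
    st <- step_annual(sys, X, u0, xi0)
    expect_lt(max(abs(st$X - X) / pmax(X, 1e-12)), 1e-10)
  }
})

test_that("annual step moves carbon as a per-flux bookkeeping oracle does", {
  expect_error(step_annual(one_pool(0.5), matrix(10, 1, 1), 0, xi_t = 3),
               "sub-annual")
  st <- step_annual(one_pool(0.1), matrix(10, 1, 1), u_t = 0)
  expect_equal(drop(st$X), c(biomass = 9))
  expect_equal(st$respired, 1)
  for (seed in 1:10) {
    p <- sample(2:5, 1)
    sys <- random_system(p, seed)
    n <- 4
    set.seed(seed)
    X <- matrix(runif(n * p, 0, 5000), n)
    xi <- matrix(runif(n * p, 0.4, 1.1), n)
    u <- runif(n, 0, 900)
    for (k in 1:5) {
      got <- step_annual(sys, X, u, xi)
      want <- oracle_step(sys, X, u, xi)
      expect_lt(max(abs(got$X - want$X)), 1e-12 * max(1, max(want$X)))
      expect_lt(max(abs(got$respired - want$respired)), 1e-12)
      X <- got$X
    }
  }
})

test_that("transient runs conserve mass and respond to forcing changes", {
  sys <- default_pool_system()
  n <- 9
  set.seed(1)
  u <- runif(n, 100, 900)
  # constant forcing from spin-up -> constant trajectory
  fc <- forcing_set(2001:2020, matrix(u, 20, n, byrow = TRUE))
  X0 <- spinup_state(sys, fc)
  tr <- run_transient(sys, X0, fc)
  expect_lt(max(abs(sweep(tr$X, c(2, 3), X0))), 1e-6)
  expect_lt(max(mass_balance_error(tr)), 1e-8)

  # step increase in influx: total C rises monotonically toward the new
  # analytic steady state
  fc2 <- forcing_set(2001:2300, matrix(u * 1.5, 300, n, byrow = TRUE))
  tr2 <- run_transient(sys, X0, fc2)
  tot <- apply(tr2$X, 1, sum)
  expect_true(all(diff(tot) > -1e-9))
  target <- sum(steady_state(sys, u * 1.5))
  expect_true(all(tot <= target + 1e-6))
  # 300 years closes most of the gap; the passive pool (500-yr residence)
  # keeps a small remainder
  expect_lt(abs(tot[300] - target) / target, 0.05)
  expect_lt(abs(tot[300] - target), 0.3 * abs(tot[1] - target))

  # linearity: influx a*U gives a * trajectory
  tr3 <- run_transient(sys, 2 * X0,
                       forcing_set(2001:2020, 2 * fc$U))
  expect_equal(tr3$X, 2 * tr$X, tolerance = 1e-12)

  # doubling xi at fixed influx halves the single-pool steady state
  sp <- one_pool(0.3)
  expect_equal(steady_state(sp, 10, xi0 = 2), steady_state(sp, 10) / 2)
})

test_that("NBP aggregates the net flux and matches the stored-carbon change", {
  sys <- one_pool(0.5)
  dom <- grid_domain(area = 1e12, land_cover_class = 1)
  # stock 200 at K=0.5 -> efflux 100; influx 110 -> NBP 0.01 PgC
  fc <- forcing_set(2000, matrix(110, 1, 1))
  tr <- run_transient(sys, matrix(200, 1, 1), fc)
  expect_equal(unname(nbp_series(tr, dom)), 0.01)

  cfg <- small_config()
  dom2 <- make_domain(cfg)
  truth <- make_truth(cfg, dom2)
  nbp <- nbp_series(truth$trajectory, dom2)
  tot <- apply(truth$trajectory$X, 1, function(x)
    sum(x * dom2$cells$area)) * 1e-15
  tot0 <- sum(truth$trajectory$X0 * dom2$cells$area) * 1e-15
  expect_equal(unname(nbp), unname(diff(c(tot0, tot))), tolerance = 1e-8)

  # steady-state run -> NBP 0 every year
  u <- truth$forcing$U[1, ]
  fcs <- forcing_set(1901:1910, matrix(u, 10, length(u), byrow = TRUE))
  trs <- run_transient(sys = truth$system, spinup_state(truth$system, fcs), fcs)
  expect_lt(max(abs(nbp_series(trs, dom2))), 1e-10)
})

test_that("stock summaries split aboveground biomass from soil carbon", {
  sys <- default_pool_system()
  u <- c(300, 600)
  fc <- forcing_set(2001:2010, matrix(u, 10, 2, byrow = TRUE))
  X0 <- spinup_state(sys, fc)
  tr <- run_transient(sys, X0, fc)
  st <- stock_summaries(tr, sys, 2001:2010)
  # AGB excludes the root pool
  expect_equal(st$agb, X0[, "leaf"] + X0[, "wood"], tolerance = 1e-8)
  expect_false(isTRUE(all.equal(st$agb, st$agb + X0[, "root"])))
  expect_equal(st$soil_c, rowSums(X0[, 4:8]), tolerance = 1e-8)
  # single-year window equals that year's stocks
  st1 <- stock_summaries(tr, sys, 2003)
  expect_equal(st1$agb, tr$X["2003", , "leaf"] + tr$X["2003", , "wood"])
  expect_error(stock_summaries(tr, sys, 1990:1991), "absent")
})
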