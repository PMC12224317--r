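test_that("single-exponential fit recovers generating parameters exactly", {
  t <- seq(0, 1, length.out = 200)
  tr <- faoTrace(t, 0.1 * exp(-5 * t) + 0.3)
  f <- fitExponential(tr, 1)
  expect_equal(f$dA, 0.1, tolerance = 1e-6)
  expect_equal(f$k_obs, 5, tolerance = 1e-6)
  expect_equal(f$A_inf, 0.3, tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("biexponential fit round-trips noiselessly and ranks phases", {
  t <- seq(0, 1, length.out = 400)
  y <- 0.06 * exp(-50 * t) + 0.04 * exp(-8 * t) + 0.2
  f <- fitExponential(faoTrace(t, y), 2)
  expect_equal(f$dA1, 0.06, tolerance = 1e-6)
  expect_equal(f$k_obs1, 50, tolerance = 1e-6)
  expect_equal(f$dA2, 0.04, tolerance = 1e-6)
  expect_equal(f$k_obs2, 8, tolerance = 1e-6)
  expect_equal(f$A_inf, 0.2, tolerance = 1e-6)
  expect_gt(f$k_obs1, f$k_obs2)   # ordering convention
})

test_that("noisy biexponential parameters are recovered within 5%", {
  t <- seq(0, 1, length.out = 600)
  y <- 0.06 * exp(-50 * t) + 0.04 * exp(-8 * t) + 0.2
  set.seed(42)
  yn <- y + rnorm(length(t), 0, 0.002)
  f <- fitExponential(faoTrace(t, yn), 2)
  expect_equal(f$k_obs1, 50, tolerance = 0.05)
  expect_equal(f$k_obs2, 8, tolerance = 0.05)
  expect_equal(f$dA1, 0.06, tolerance = 0.05)
  expect_equal(f$dA2, 0.04, tolerance = 0.05)
})

test_that("fit guards: short traces and invalid phase counts are rejected", {
  t <- seq(0, 1, length.out = 8)
  tr <- faoTrace(t, exp(-t))
  expect_error(fitExponential(tr, 3), "n_phases")
  expect_error(faoTrace(1:5, 1:5), ">= 8 points")
  expect_error(faoTrace(c(1, 1, 2:7), rep(0, 8)), "increasing")
})

test_that("phase-count selection obeys the information-criterion and amplitude rules", {
  t <- seq(0, 2, length.out = 300)
  mono <- faoTrace(t, 0.1 * exp(-3 * t) + 0.2)
  expect_identical(as.integer(selectPhaseCount(mono)), 1L)

  bi <- faoTrace(t, 0.05 * exp(-18 * t) + 0.05 * exp(-3 * t) + 0.2)
  expect_identical(as.integer(selectPhaseCount(bi)), 2L)

  # second amplitude buried below the 3-sigma floor reverts to one phase
  set.seed(7)
  tiny <- 0.1 * exp(-3 * t) + 0.003 * exp(-30 * t) + 0.2 +
    rnorm(length(t), 0, 0.002)
  expect_identical(as.integer(selectPhaseCount(faoTrace(t, tiny))), 1L)
})

test_that("phase ordering is invariant to initializer labelling", {
  t <- seq(0, 1, length.out = 300)
  y <- 0.03 * exp(-40 * t) + 0.07 * exp(-6 * t) + 0.1
  f <- fitExponential(faoTrace(t, y), 2)
  expect_gt(f$k_obs1, f$k_obs2)
  expect_equal(f$k_obs1, 40, tolerance = 1e-6)
  expect_equal(f$dA1, 0.03, tolerance = 1e-6)
})

test_that("bimolecular fit equals the normal-equations closed form", {
  # two-point line through the origin
  b <- fitBimolecular(c(100e-6, 200e-6), c(10, 20))
  expect_equal(b$k_ox, 1e5, tolerance = 1e-12)
  expect_equal(b$intercept, 0, tolerance = 1e-9)

  # collinear points with intercept 2 recovered exactly
  conc <- c(1, 2, 3, 4) * 1e-4
  kobs <- 2 + 5e4 * conc
  b2 <- fitBimolecular(conc, kobs)
  expect_equal(b2$k_ox, 5e4, tolerance = 1e-9)
  expect_equal(b2$intercept, 2, tolerance = 1e-9)

  # general noisy case matches the normal equations to machine precision
  set.seed(1)
  x <- runif(6, 1e-5, 1e-3); y <- 3 + 2e4 * x + rnorm(6, 0, 0.5)
  b3 <- fitBimolecular(x, y)
  ne <- unname(normalEquationsOracle(x, y))
  expect_equal(b3$intercept, ne[1], tolerance = 1e-10)
  expect_equal(b3$k_ox, ne[2], tolerance = 1e-10)

  expect_error(fitBimolecular(c(1e-4, 1e-4), c(1, 2)), "identical")
  expect_error(fitBimolecular(1e-4, 1), ">= 2")
})

test_that("end-to-end O2 recovery returns the generating constant within 2%", {
  sch <- kineticScheme(k_O2 = 27)
  concs <- c(130, 260, 390, 605) * 1e-6
  kobs <- vapply(concs, function(C) {
    tg <- logGrid(27 * C)
    traj <- simulateMechanism(sch, mixState(FlH2 = 5e-6, O2 = C), tg)
    fitExponential(absorbanceTrace(traj, spectralModel(), 450), 1)$k_obs
  }, numeric(1))
  b <- fitBimolecular(concs, kobs)
  expect_equal(b$k_ox, 27, tolerance = 0.02)
})

test_that("pseudo-first-order bias is negative at modest excess and vanishes in the limit", {
  sch <- kineticScheme(k1f = 1e6, k2f = 2.7e5)
  # 18 uM enzyme vs 40-80 uM oxidant: the accessible regime, slope biased low
  bias_low <- pseudoFirstOrderBias(sch, 18e-6, c(40, 60, 80) * 1e-6,
                                   n_t = 400)
  expect_lt(as.numeric(bias_low), 0)

  # large excess: bias within 2% of zero
  bias_high <- pseudoFirstOrderBias(sch, 1e-6, c(0.5, 0.75, 1) * 1e-3,
                                    n_t = 400)
  expect_lt(abs(as.numeric(bias_high)), 0.02)

  # bias nondecreasing over an excess ladder (to within the ~0.5% noise
  # floor of the fit-and-regress procedure itself)
  mid <- pseudoFirstOrderBias(sch, 18e-6, c(200, 300, 400) * 1e-6, n_t = 400)
  expect_true(as.numeric(bias_low) <= as.numeric(mid) + 0.005)
  expect_true(as.numeric(mid) <= as.numeric(bias_high) + 0.005)
})
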