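test_that("constructors reject invalid schemes and states", {
  expect_error(kineticScheme(k_O2 = -1), "k_O2")
  expect_error(kineticScheme(K1 = 0), "K1")
  expect_error(mixState(FlH2 = -1e-6), "negative")
  expect_error(mixState(FlH2 = 1e-6, O2 = 1e-6, Cox = 1e-6), "one oxidant")
  expect_error(spectralModel(eps450_Flox = -5), "extinction")
})

test_that("no reaction without rate constants or oxidant", {
  tg <- seq(0, 1, length.out = 11)
  init <- mixState(FlH2 = 18e-6, Cox = 60e-6)
  traj <- simulateMechanism(kineticScheme(), init, tg)
  for (sp in c("FlH2", "Cox"))
    expect_equal(traj[[sp]], rep(init[[sp]], 11))

  sch <- kineticScheme(k_O2 = 1e3, k1f = 1e6, k2f = 1e5)
  traj2 <- simulateMechanism(sch, mixState(FlH2 = 18e-6), tg)
  expect_equal(traj2$FlH2, rep(18e-6, 11), tolerance = 1e-9)
})

test_that("irreversible excess-oxidant kinetics match the sequential-decay closed form", {
  k1f <- 1e6; k2f <- 2e5
  conc <- 2e-3; E0 <- 1e-8          # 200,000-fold oxidant excess
  sch <- kineticScheme(k1f = k1f, k2f = k2f, K1 = Inf, K2 = Inf)
  tg <- logGrid(k2f * conc, n = 300)
  traj <- simulateMechanism(sch, mixState(FlH2 = E0, Cox = conc), tg)
  oracle <- sequentialDecayOracle(E0, k1f * conc, k2f * conc, tg)
  scale <- E0
  expect_lt(max(abs(traj$FlH2 - oracle$A)) / scale, 1e-3)
  expect_lt(max(abs(traj$FlSQ - oracle$B)) / scale, 1e-3)
})

test_that("conservation laws hold along trajectories of both branches", {
  tg <- seq(0, 2, length.out = 101)
  sch <- kineticScheme(k1f = 1e6, k2f = 2.7e5, K1 = 10, K2 = 10)
  traj <- simulateMechanism(sch, mixState(FlH2 = 18e-6, Cox = 60e-6), tg)
  enz <- traj$FlH2 + traj$FlSQ + traj$Flox
  cyt <- traj$Cox + traj$Cred
  elec <- 2 * traj$FlH2 + traj$FlSQ + traj$Cred + 2 * traj$H2O2
  expect_lt(max(abs(enz - enz[1])), 1e-9)
  expect_lt(max(abs(cyt - cyt[1])), 1e-9)
  expect_lt(max(abs(elec - elec[1])), 1e-9)

  scho <- kineticScheme(k_O2 = 1e3)
  trajo <- simulateMechanism(scho, mixState(FlH2 = 18e-6, O2 = 130e-6), tg)
  eleco <- 2 * trajo$FlH2 + trajo$FlSQ + trajo$Cred + 2 * trajo$H2O2
  expect_lt(max(abs(eleco - eleco[1])), 1e-9)
  # O2-branch 450 nm trace is monotone nondecreasing
  a450 <- absorbanceTrace(trajo, spectralModel(), 450)
  expect_true(all(diff(a450$absorbance) >= -1e-12))
})

test_that("equilibrium endpoint solves the mass-action conditions", {
  # single-step variant, K1 = 1, equal 18 uM pools: x^2 = (18 - x)^2 => 9 uM
  sch <- kineticScheme(k1f = 1e6, k2f = 0, K1 = 1)
  eq <- equilibriumEndpoint(sch, mixState(FlH2 = 18e-6, Cox = 18e-6))
  expect_equal(eq[["FlSQ"]], 9e-6, tolerance = 1e-6)
  expect_equal(eq[["Cred"]], 9e-6, tolerance = 1e-6)

  # irreversible with excess oxidant: fully oxidized
  schi <- kineticScheme(k1f = 1e6, k2f = 1e5, K1 = Inf, K2 = Inf)
  eqi <- equilibriumEndpoint(schi, mixState(FlH2 = 18e-6, Cox = 60e-6))
  expect_equal(eqi[["Flox"]], 18e-6, tolerance = 1e-9)
  expect_equal(eqi[["FlH2"]], 0, tolerance = 1e-12)

  # a state already at equilibrium is a fixed point
  schr <- kineticScheme(k1f = 1e6, k2f = 2.7e5, K1 = 10, K2 = 10)
  eq1 <- equilibriumEndpoint(schr, mixState(FlH2 = 18e-6, Cox = 40e-6))
  eq2 <- equilibriumEndpoint(schr, eq1)
  expect_equal(as.numeric(eq2), as.numeric(eq1), tolerance = 1e-7)

  # equals the long-time limit of the simulator
  traj <- simulateMechanism(schr, mixState(FlH2 = 18e-6, Cox = 40e-6),
                            seq(0, 50, length.out = 51))
  final <- unlist(traj[nrow(traj), c("FlH2", "FlSQ", "Flox", "Cox", "Cred")])
  expect_equal(unname(final),
               as.numeric(eq1)[1:5], tolerance = 1e-6)
})

test_that("absorbance traces follow Beer-Lambert sums", {
  tg <- seq(0, 1, length.out = 11)
  traj <- simulateMechanism(kineticScheme(), mixState(Flox = 18e-6), tg)
  zero <- spectralModel(eps450_Flox = 0, eps450_FlH2 = 0, eps450_FlSQ = 0,
                        eps550_Cred = 0, eps550_Cox = 0, eps550_FlSQ = 0)
  expect_equal(absorbanceTrace(traj, zero, 450)$absorbance, rep(0, 11))
  # 18 uM oxidized flavin at 450 nm: 11300 * 18e-6 = 0.2034 AU
  a <- absorbanceTrace(traj, spectralModel(), 450)
  expect_equal(a$absorbance, rep(0.2034, 11), tolerance = 1e-12)
  expect_error(absorbanceTrace(traj, spectralModel(), 410), "wavelength")
})

test_that("concentration estimation inverts the extinction coefficients", {
  expect_equal(estimateConcentration(0, "FAO"), 0)
  expect_equal(estimateConcentration(0.4068, "FAO"), 36e-6)
  expect_equal(estimateConcentration(1.06, "CytC"), 10e-6)
  expect_error(estimateConcentration(0.1, "heme"), "unknown role")
  expect_error(estimateConcentration(-0.1, "FAO"), ">= 0")
})
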