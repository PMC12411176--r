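test_that("the biomass pseudo-reaction converts grams to moles exactly", {
  w <- c(A = 150, B = 100, C = 100, D = 200)
  fr <- c(A = 0.35, B = 0.15, C = 0.3, D = 0.2)
  bio <- biomassPseudoreaction(fr, w)
  expect_equal(bio$coefficients[["A"]], 7 / 3000)       # 2.33e-3 mol/gDW
  expect_equal(bio$coefficients[["B"]], 1.5e-3)
  expect_equal(bio$coefficients[["C"]], 3e-3)
  expect_equal(bio$coefficients[["D"]], 1e-3)
  expect_equal(bio$massPerUnit, 1)                      # 1 g per unit flux
  expect_true(all(bio$stoich < 0))
  ## closure holds for any admissible composition
  set.seed(8)
  for (i in 1:10) {
    f2 <- runif(4); f2 <- f2 / sum(f2); names(f2) <- names(w)
    expect_equal(biomassPseudoreaction(f2, w)$massPerUnit, 1,
                 tolerance = 1e-12)
  }
  expect_error(biomassPseudoreaction(c(A = 0.4, B = 0.6), c(A = 10)),
               "missing molecular weight")
  expect_error(biomassPseudoreaction(c(A = 0.5), w), "sum to 1")
})

test_that("M = I - c w' reproduces the dilution-corrected steady state", {
  w <- c(150, 100, 100, 200)
  expect_equal(buildMMatrix(rep(0, 4), w), diag(4))   # c = 0: plain FBA
  net <- toyNetwork()
  N <- stoichiometry(net)
  set.seed(3)
  for (i in 1:10) {
    conc <- runif(4, 0, 0.05)
    M <- buildMMatrix(conc, w)
    r <- rnorm(7)
    mu <- growthRateFromFluxes(net, r)
    expect_equal(as.numeric(M %*% N %*% r),
                 as.numeric(N %*% r) - mu * conc, tolerance = 1e-9)
  }
  ## full mass accounted (w'c = 1 g/g): w'M = 0, so w'MNr = 0 for all r
  conc <- c(2, 1, 3, 2); conc <- conc * 1000 / sum(conc * w)
  M <- buildMMatrix(conc, w)
  expect_lt(max(abs(crossprod(w, M))), 1e-12)
  expect_error(buildMMatrix(1:3, w), "equal length")
})

test_that("unit synthesis rates scale with the mass fractions", {
  um <- unitNetwork("three-unit")$unitModel
  ss <- unitSteadyState(um, 0)
  expect_equal(ss$rsyn, rep(0, 3))
  ss <- unitSteadyState(um, 0.8)
  expect_equal(ss$rsyn, 0.8 * um@units$massFraction)
  ## ratios of synthesis rates equal ratios of fractions (r3 = r2 B2/B1)
  expect_equal(ss$rsyn[2], ss$rsyn[1] * ss$massFraction[2] /
                 ss$massFraction[1])
  expect_error(unitSteadyState(um, -1), "non-negative")
})

test_that("the mass-fraction network's growth mode has unit synthesis rates", {
  fx <- unitNetwork("two-unit-massfrac", fB1 = 0.4)
  N <- stoichiometry(fx$network)
  w <- molecularWeights(fx$network)
  cmol <- c(A = 0, B1 = 0.4 / w[["B1"]], B2 = 0.6 / w[["B2"]])  # mol/gDW
  M <- diag(3) - outer(cmol, w)     # mol basis, so no mmol factor
  MN <- M %*% N
  expect_identical(ncol(rankAndNullspace(MN)$basis), 2L)
  ## overflow mode: substrate straight through, no synthesis
  over <- c(1, 1, 0, 0)
  expect_lt(max(abs(MN %*% over)), 1e-12)
  ## growth mode (r1 = 0, s1 = 1): both synthesis rates are 1 and the
  ## uptake equals 1/wA
  A <- rbind(MN, c(0, 1, 0, 0), c(0, 0, 1, 0))
  v <- qr.solve(A, c(0, 0, 0, 0, 1))
  expect_equal(v, c(1 / w[["A"]], 0, 1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the two-unit growth mode keeps the printed mass-coupling", {
  fx <- unitNetwork("two-unit")
  N <- stoichiometry(fx$network)
  w <- molecularWeights(fx$network)
  B1 <- 0.55; B2 <- 0.45
  cmmol <- c(A = 0, B1 = B1 * 1000 / w[["B1"]], B2 = B2 * 1000 / w[["B2"]])
  M <- buildMMatrix(cmmol, w)
  MN <- M %*% N
  ## growth mode with no overflow: synthesis mass ratio = fraction ratio
  A <- rbind(MN, c(0, 1, 0, 0), c(0, 0, 1, 0))
  v <- qr.solve(A, c(0, 0, 0, 0, 1))
  massR2 <- v[3] * w[["B1"]]
  massR3 <- v[4] * w[["B2"]]
  expect_equal(unname(massR3 / massR2), B2 / B1, tolerance = 1e-9)
})

test_that("the allocation scan hits the uptake/synthesis crossover", {
  scan <- reducedAllocationScan(k1 = 100, k2 = 1.2, grid = 801)
  i <- attr(scan, "optimum")
  ## boundary states cannot grow
  expect_equal(scan$mu[1], 0)                    # B1 = 0: no uptake
  expect_equal(scan$mu[nrow(scan)], 0)           # B2 = 0: no synthesis
  expect_true(all(scan$r1 >= -1e-9))
  ## 1-D continuous oracle: golden-section on the realized growth rate
  f <- function(B1) min(150 * 100 * B1 / 1000, 1.2 * (1 - B1))
  o <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-10)
  expect_lt(abs(scan$B1[i] - o$maximum), 2 / 800)
  expect_equal(scan$mu[i], o$objective, tolerance = 1e-3)
  ## overflow vanishes at the optimum
  expect_equal(scan$r1[i], 0, tolerance = 0.2)
})

test_that("substrate limitation saturates and burden reduces growth", {
  lim <- scenarioSweep("substrate_limitation", values = c(0.1, 0.3, 1, 3, 10),
                       grid = 801)
  expect_true(all(diff(lim$mu) >= -1e-9))        # more substrate never hurts
  ## hyperbolic approach to a plateau: increments shrink
  inc <- diff(lim$mu)
  expect_true(all(diff(inc) < 0))
  expect_lt(lim$mu[5] - lim$mu[4], 0.2 * (lim$mu[2] - lim$mu[1]))
  burden <- scenarioSweep("heterologous_burden",
                          values = c(0, 0.2, 0.4, 0.6, 0.8), grid = 801)
  expect_true(all(diff(burden$mu) <= 1e-9))      # burden never helps
  expect_gt(burden$mu[1], burden$mu[5])
})
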