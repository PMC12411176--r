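test_that("Michaelis-Menten saturates between 0 and kcat E", {
  law <- kineticLaw(100, Km = 0.5)
  E <- 0.01
  expect_equal(mmRate(law, E, 0.5), 100 * E / 2)   # half saturation at Km
  expect_equal(mmRate(law, E, 0), 0)
  expect_lt(mmRate(law, E, 1e6), 100 * E)
  expect_equal(mmRate(law, E, 1e9), 100 * E, tolerance = 1e-6)
  expect_error(mmRate(law, E, -1), "non-negative")
  expect_error(mmRate(kineticLaw(100, Ks = c(S = 1)), E, 1), "Km")
})

test_that("the reversible rate vanishes exactly at equilibrium", {
  set.seed(4)
  for (i in 1:20) {
    law <- kineticLaw(exp(runif(1, 0, 5)), Ks = c(S = runif(1, 0.1, 2)),
                      Kp = c(P = runif(1, 0.1, 2)), Keq = exp(runif(1, -2, 2)))
    S <- runif(1, 0.05, 3)
    expect_equal(reversibleRate(law, 1e-3, S, S * law@Keq), 0,
                 tolerance = 1e-12)
    ## sign(r) = sign(1 - Q/Keq)
    expect_gt(reversibleRate(law, 1e-3, S, S * law@Keq * 0.5), 0)
    expect_lt(reversibleRate(law, 1e-3, S, S * law@Keq * 2), 0)
  }
})

test_that("the single-substrate form reduces to the printed denominator", {
  law <- kineticLaw(1e6, Ks = c(S = 1), Kp = c(P = 1), Keq = 1)
  ## s = 1, p = 0: denominator (1+s) + (1+p) - 1 = 2, thermo term 1
  expect_equal(reversibleRate(law, 2e-6, 1, 0), 1e6 * 2e-6 / 2)
  ## forward rates are capped by kcat E; reverse rates by the Haldane
  ## backward capacity kcat Kp / (Ks Keq)
  set.seed(9)
  for (i in 1:50) {
    law <- kineticLaw(1e4, Ks = c(S = runif(1, 0.1, 2)),
                      Kp = c(P = runif(1, 0.1, 2)),
                      Keq = exp(runif(1, -3, 3)))
    r <- reversibleRate(law, 1e-3, runif(1, 0, 5), runif(1, 0, 5))
    capF <- 1e4 * 1e-3
    capB <- capF * law@Kp[[1]] / (law@Ks[[1]] * law@Keq)
    expect_lte(r, capF + 1e-12)
    expect_gte(r, -capB - 1e-12)
  }
})

test_that("rate decomposition reassembles the rate exactly", {
  set.seed(21)
  for (i in 1:200) {
    nS <- sample(1:2, 1); nP <- sample(1:2, 1)
    law <- kineticLaw(exp(runif(1, 0, 8)),
                      Ks = setNames(runif(nS, 0.1, 3), paste0("S", 1:nS)),
                      Kp = setNames(runif(nP, 0.1, 3), paste0("P", 1:nP)),
                      orderS = setNames(sample(1:2, nS, TRUE),
                                        paste0("S", 1:nS)),
                      orderP = setNames(sample(1:2, nP, TRUE),
                                        paste0("P", 1:nP)),
                      Keq = exp(runif(1, -3, 3)))
    E <- runif(1, 1e-6, 1e-3)
    S <- runif(nS, 0.01, 4); P <- runif(nP, 0.01, 4)
    d <- rateDecomposition(law, E, S, P)
    expect_equal(d$etaC * d$etaS * d$etaT, reversibleRate(law, E, S, P),
                 tolerance = 1e-12)
    expect_gte(d$etaS, 0); expect_lte(d$etaS, 1)
    expect_equal(d$etaC, law@kcat * E)
    ## eta_t = 1 - exp(dG*) with dG* = ln(Q/Keq)
    Q <- prod(P^law@orderP) / prod(S^law@orderS)
    expect_equal(d$etaT, 1 - exp(log(Q / law@Keq)), tolerance = 1e-9)
  }
  law <- kineticLaw(10, Ks = c(S = 1), Kp = c(P = 1), Keq = 2)
  expect_equal(rateDecomposition(law, 1, 1, 0)$etaT, 1)   # Q = 0
  expect_equal(rateDecomposition(law, 1, 1, 2)$etaT, 0)   # equilibrium
})

test_that("rates increase in substrates and decrease in products", {
  law <- kineticLaw(1e4, Ks = c(S = 1), Kp = c(P = 1), Keq = 2)
  set.seed(33)
  for (i in 1:40) {
    S <- runif(1, 0.1, 3); P <- runif(1, 0.1, 3)
    h <- 1e-6
    dS <- (reversibleRate(law, 1, S + h, P) -
             reversibleRate(law, 1, S, P)) / h
    dP <- (reversibleRate(law, 1, S, P + h) -
             reversibleRate(law, 1, S, P)) / h
    expect_gt(dS, 0)
    expect_lt(dP, 0)
  }
})

test_that("Haldane-consistent parameters put the zero crossing at Keq", {
  expect_equal(haldaneKeq(2, 1, 1, 1), 2)
  expect_equal(haldaneKeq(5, 5, 0.3, 0.3), 1)   # symmetric enzyme
  expect_error(haldaneKeq(-1, 1, 1, 1), "positive")
  set.seed(5)
  for (i in 1:10) {
    kp <- runif(1, 1, 10); km <- runif(1, 1, 10)
    Ks <- runif(1, 0.2, 2); Kp <- runif(1, 0.2, 2)
    keq <- haldaneKeq(kp, km, Ks, Kp)
    law <- kineticLaw(kp, Ks = c(S = Ks), Kp = c(P = Kp), Keq = keq,
                      kcatMinus = km)
    S <- runif(1, 0.1, 2)
    expect_equal(reversibleRate(law, 1, S, S * keq), 0, tolerance = 1e-12)
  }
})

test_that("enzyme demand inverts the rate law and diverges at equilibrium", {
  law <- kineticLaw(1e6, Ks = c(S = 1), Kp = c(P = 1), Keq = 1)
  ## r = 1 at s = 1, P = 0: eta_s = 1/2, eta_t = 1 -> E = 2e-6
  expect_equal(enzymeDemand(law, 1, 1, 0), 2e-6, tolerance = 1e-12)
  ## demand rises monotonically to infinity as P/S approaches Keq
  ps <- c(0, 0.5, 0.9, 0.99, 0.999)
  dem <- vapply(ps, function(p) enzymeDemand(law, 1, 1, p), 0)
  expect_true(all(diff(dem) > 0))
  expect_gt(dem[5] / dem[1], 100)
  expect_error(enzymeDemand(law, 1, 1, 1.5), "infeasible")
  ## linear in the target flux
  expect_equal(enzymeDemand(law, 3, 1, 0.4),
               3 * enzymeDemand(law, 1, 1, 0.4), tolerance = 1e-12)
})

test_that("eta_t agrees with the network Gibbs energies", {
  ## cross-module consistency: eta_t = 1 - exp(dG/RT) for r3 (C <-> B)
  net <- toyNetwork()
  spec <- toyThermoSpec(net)
  x <- c(A = log(0.02), B = log(0.05), C = log(0.01), D = log(0.03))
  dg <- scaledDeltaG(spec, net, x)$dg
  law <- kineticLaw(10, Ks = c(C = 1), Kp = c(B = 1), Keq = 3)
  d <- rateDecomposition(law, 1, exp(x[["C"]]), exp(x[["B"]]))
  expect_equal(d$etaT, 1 - exp(dg[["r3"]] / spec@RT), tolerance = 1e-9)
})

test_that("non-integer molecularities are rejected", {
  expect_error(kineticLaw(10, Ks = c(S = 1), orderS = c(S = 1.5)),
               "positive integers")
  expect_error(kineticLaw(10, Ks = c(S = -1)), "positive")
})
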