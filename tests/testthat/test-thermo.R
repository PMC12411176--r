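test_that("Keq and dG0' interconvert consistently", {
  RT <- 8.315e-3 * 300
  expect_equal(keqToDg0(1), 0)
  expect_lt(keqToDg0(5), 0)          # Keq > 1 -> negative standard value
  expect_gt(keqToDg0(0.2), 0)
  for (keq in c(1e-3, 0.5, 1, 7, 1e4))
    expect_equal(dg0ToKeq(keqToDg0(keq)), keq, tolerance = 1e-12)
  expect_error(keqToDg0(-1), "positive")
  ## one decade of Keq shifts dG by RT ln 10
  expect_equal(keqToDg0(1) - keqToDg0(10), RT * log(10))
})

test_that("Gibbs energies vanish at equilibrium concentrations", {
  net <- toyNetwork()
  spec <- toyThermoSpec(net)
  ## all-zero x with dG0' = 0 gives dG = 0
  z <- thermoSpec(setNames(numeric(4), c("r1", "r2", "r3", "r4")), net = net)
  x0 <- setNames(numeric(4), c("A", "B", "C", "D"))
  expect_equal(unname(scaledDeltaG(z, net, x0)$dg), rep(0, 4))
  ## pick concentrations with mass-action ratio = Keq for r3 (C <-> B):
  ## ln(B/C) = ln Keq3
  x <- c(A = 0, B = log(3), C = 0, D = 0)
  dg <- scaledDeltaG(spec, net, x)$dg
  expect_equal(dg[["r3"]], 0, tolerance = 1e-12)
  ## shifting Keq by one decade moves dG by RT ln 10 = 5.75 kJ/mol
  spec10 <- thermoSpec(keqToDg0(toyKeq * 10), net = net)
  dg10 <- scaledDeltaG(spec10, net, x)$dg
  expect_equal(unname(dg - dg10), rep(spec@RT * log(10), 4))
  expect_equal(spec@RT * log(10), 5.7438, tolerance = 1e-4)
  noDg <- thermoSpec(c(r1 = 0), net = net)
  expect_error(scaledDeltaG(noDg, net, x0), "r2")
})

test_that("loop-law consistency holds iff the Keq identity holds", {
  net <- toyNetwork()
  cb <- internalCycleBasis(net)
  ## Keq4 = Keq2 * Keq3^2 = 18: consistent
  expect_true(checkCycleConsistency(toyThermoSpec(net), cb)$consistent)
  bad <- thermoSpec(keqToDg0(c(r1 = 10, r2 = 2, r3 = 3, r4 = 17)), net = net)
  expect_false(checkCycleConsistency(bad, cb)$consistent)
  ## explicit identity: -dG2 - 2 dG3 + dG4 = 0
  dg0 <- keqToDg0(toyKeq)
  expect_equal(-dg0[["r2"]] - 2 * dg0[["r3"]] + dg0[["r4"]], 0,
               tolerance = 1e-12)
  ## cycle-free network is trivially consistent
  chain <- metabolicNetwork(
    matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "v1")),
    internal = TRUE)
  spec <- thermoSpec(c(v1 = -3), net = chain)
  expect_true(checkCycleConsistency(spec,
                                    internalCycleBasis(chain))$consistent)
})

test_that("the sign-vector test separates loop-free flux patterns", {
  sc <- c(0, -1, -1, 1)            # signs of the cycle basis vector
  expect_equal(signLoopTest(sc, sc)$rhs, 3)
  st <- signLoopTest(sc, c(0, 1, 1, 1))
  expect_equal(st$lhs, 1)
  expect_true(st$passes)
  ## a flux running in the cycle makes both sides equal
  st2 <- signLoopTest(sc, sc)
  expect_equal(st2$lhs, st2$rhs)
  expect_false(st2$passes)
  expect_error(signLoopTest(sc, c(1, 0)), "equal length")
  expect_error(signLoopTest(sc, c(0, 2, 0, 0)), "-1, 0")
})

test_that("loopless FBA removes the cycle and respects dG sign coupling", {
  net <- toyNetwork()
  spec <- toyThermoSpec(net)
  obj <- fluxObjective("linear", c(r3 = 1))
  plain <- solveFBA(net, obj, fixed = list(r0 = 1), tieBreak = FALSE)
  ll <- looplessFBA(net, obj, spec, fixed = list(r0 = 1))
  expect_identical(solutionStatus(ll), "optimal")
  ## the objective is no longer pinned at the flux bound
  expect_lt(objectiveValue(ll), objectiveValue(plain))
  ## constraint addition can only lower the optimum
  expect_lte(objectiveValue(ll), objectiveValue(plain) + 1e-9)
  ## every basis cycle passes the sign test
  K <- internalCycleBasis(net)$basis
  ids <- rownames(K)
  sf <- sign(round(fluxes(ll)[ids], 9))
  for (k in seq_len(ncol(K)))
    expect_true(signLoopTest(sign(round(K[, k], 9)), unname(sf))$passes)
  ## dG r < 0 for all running internal reactions, and K' dG = 0
  dg <- deltaG(ll)
  run <- abs(fluxes(ll)[ids]) > 1e-9
  expect_true(all((dg[run] * fluxes(ll)[ids][run]) < 0))
  expect_lt(max(abs(crossprod(K, dg))), 1e-6)
})

test_that("loopless FBA on a cycle-free network equals plain FBA", {
  chain <- metabolicNetwork(
    matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE,
           dimnames = list(c("A", "B"), c("v0", "v1", "v2"))),
    lb = c(0, -10, 0), ub = 10, internal = c(FALSE, TRUE, FALSE))
  spec <- thermoSpec(c(v1 = -5), net = chain)
  obj <- fluxObjective("linear", c(v2 = 1))
  plain <- solveFBA(chain, obj, fixed = list(v0 = 2))
  ll <- looplessFBA(chain, obj, spec, fixed = list(v0 = 2))
  expect_equal(objectiveValue(ll), objectiveValue(plain), tolerance = 1e-8)
})

test_that("an in-cycle sign pattern admits no concentration assignment", {
  net <- toyNetwork()
  spec <- toyThermoSpec(net)
  obj <- fluxObjective("linear", c(r3 = 1))
  ## r2 > 0, r3 > 0, r4 < 0: flux runs around the cycle
  bad <- tfbaWithConcentrations(net, obj, spec,
                                signs = c(r1 = 1, r2 = 1, r3 = 1, r4 = -1))
  expect_identical(solutionStatus(bad), "infeasible")
  expect_true(length(attr(bad, "violatedCycles")) > 0)
  ## a loop-free pattern is feasible and satisfies dG r < 0
  ll <- looplessFBA(net, obj, spec, fixed = list(r0 = 1))
  sf <- sign(round(fluxes(ll)[c("r1", "r2", "r3", "r4")], 9))
  ok <- tfbaWithConcentrations(net, obj, spec, signs = sf)
  expect_identical(solutionStatus(ok), "optimal")
  dg <- deltaG(ok)
  r <- fluxes(ok)[names(dg)]
  expect_true(all(dg[abs(r) > 1e-9] * r[abs(r) > 1e-9] < 0))
  expect_true(all(logConcentrations(ok) >= spec@xMin - 1e-9))
  expect_true(all(logConcentrations(ok) <= spec@xMax + 1e-9))
})

test_that("max-min driving force matches a grid oracle on one reaction", {
  n1 <- metabolicNetwork(
    matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "rx")),
    internal = TRUE)
  sp <- thermoSpec(c(rx = 0), xMin = c(A = -1, B = -1),
                   xMax = c(A = 1, B = 1))
  res <- mdf(n1, sp, c(rx = 1))
  ## brute force over the (x_A, x_B) box
  g <- seq(-1, 1, length.out = 201)
  oracle <- max(outer(g, g, function(xa, xb) -(sp@RT * (xb - xa))))
  expect_equal(res$B, oracle, tolerance = 1e-6)
  expect_equal(res$B, 2 * sp@RT, tolerance = 1e-6)
  ## tightening a bound never increases B
  sp2 <- thermoSpec(c(rx = 0), xMin = c(A = -1, B = -0.2),
                    xMax = c(A = 0.5, B = 1))
  expect_lte(mdf(n1, sp2, c(rx = 1))$B, res$B + 1e-9)
})

test_that("MDF improves the worst driving force of a valid flux map", {
  net <- toyNetwork()
  spec <- toyThermoSpec(net)
  ll <- looplessFBA(net, fluxObjective("linear", c(r3 = 1)), spec,
                    fixed = list(r0 = 1))
  sf <- sign(round(fluxes(ll)[c("r1", "r2", "r3", "r4")], 9))
  witness <- tfbaWithConcentrations(net, fluxObjective("linear", c(r3 = 1)),
                                    spec, signs = sf)
  run <- sf != 0
  worst <- min(-sf[run] * deltaG(witness)[run])
  res <- mdf(net, spec, sf)
  expect_identical(res$status, "optimal")
  expect_gte(res$B, worst - 1e-9)
  ## the in-cycle pattern has no positive driving force
  badRes <- mdf(net, spec, c(r1 = 1, r2 = 1, r3 = 1, r4 = -1))
  expect_identical(badRes$status, "infeasible")
})

test_that("both LP routes agree on random instances when pracma converges", {
  skip_if_not_installed("pracma")
  set.seed(11)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    cc <- rnorm(n)
    A <- matrix(rnorm(2 * n), 2)
    b <- runif(2, 1, 4)
    mine <- selfcell:::solveLP(cc, Aub = A, bub = b, lb = rep(0, n),
                               ub = rep(10, n))
    ref <- tryCatch(
      pracma::linprog(cc, A = rbind(A, diag(n)), b = c(b, rep(10, n)),
                      maxiter = 1000),
      error = function(e) NULL)
    if (is.null(ref) || is.null(ref$errno) || ref$errno != 1) next
    expect_equal(mine$value, ref$fval, tolerance = 1e-6)
  }
})
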