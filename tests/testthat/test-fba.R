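test_that("maximizing the export routes all incoming mass to Dex", {
  net <- toyNetwork()
  sol <- solveFBA(net, fluxObjective("linear", c(r5 = 1)),
                  fixed = list(r0 = 1))
  expect_identical(solutionStatus(sol), "optimal")
  ## 150 g of A per mmol input -> at most 0.75 mmol of the 200 g/mol D
  expect_equal(objectiveValue(sol), 0.75, tolerance = 1e-8)
  N <- stoichiometry(net)
  expect_lt(max(abs(N %*% fluxes(sol))), 1e-8)
  rd <- reactions(net)
  expect_true(all(fluxes(sol) >= rd$lb - 1e-8 & fluxes(sol) <= rd$ub + 1e-8))
  expect_equal(fluxes(sol)[["r0"]], 1)
})

test_that("without thermodynamics a cycle flux is pinned at its bound", {
  net <- toyNetwork()
  sol <- solveFBA(net, fluxObjective("linear", c(r3 = 1)),
                  fixed = list(r0 = 1), tieBreak = FALSE)
  expect_equal(objectiveValue(sol), reactions(net)$ub[4])
  ## r2 and r4 adjust to keep the balance: net production at B and C is 0
  r <- fluxes(sol)
  expect_lt(max(abs(stoichiometry(net) %*% r)), 1e-8)
  ## the objective is scale-free in the input flux
  sol5 <- solveFBA(net, fluxObjective("linear", c(r3 = 1)),
                   fixed = list(r0 = 5), tieBreak = FALSE)
  expect_equal(objectiveValue(sol5), objectiveValue(sol))
})

test_that("an all-zero objective is optimal at zero", {
  sol <- solveFBA(toyNetwork(), fluxObjective("linear", c(r5 = 0)))
  expect_identical(solutionStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 0)
})

test_that("minimal total flux activates exactly the direct route", {
  sol <- minimizeTotalFlux(toyNetwork(), fixed = list(r0 = 1))
  r <- fluxes(sol)
  active <- names(r)[abs(r) > 1e-9]
  expect_setequal(active, c("r0", "r5", "r6"))
  expect_equal(objectiveValue(sol), 2, tolerance = 1e-8)
  ## a single chain is unchanged by the split reformulation
  chain <- metabolicNetwork(
    matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE,
           dimnames = list(c("A", "B"), c("v0", "v1", "v2"))),
    lb = 0, ub = 10, internal = c(FALSE, TRUE, FALSE))
  sc <- minimizeTotalFlux(chain, fixed = list(v0 = 2))
  expect_equal(unname(fluxes(sc)), c(2, 2, 2))
})

test_that("LP optima dominate sampled feasible points and survive row scaling", {
  net <- toyNetwork()
  feas <- randomFeasibleFluxes(net, 8, fixed = list(r0 = 1), seed = 42)
  expect_gt(length(feas), 3)
  obj <- fluxObjective("linear", c(r5 = 1))
  opt <- objectiveValue(solveFBA(net, obj, fixed = list(r0 = 1)))
  for (r in feas) expect_lte(r[["r5"]], opt + 1e-8)
  ## scaling a mass-balance row must not change the optimum
  scaled <- net
  scaled@stoichiometry["B", ] <- 2 * scaled@stoichiometry["B", ]
  expect_equal(objectiveValue(solveFBA(scaled, obj, fixed = list(r0 = 1))),
               opt, tolerance = 1e-8)
  ## reordering reactions must not change the optimum
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  net2 <- metabolicNetwork(stoichiometry(net)[, perm],
                           mw = molecularWeights(net),
                           lb = reactions(net)$lb[perm],
                           ub = reactions(net)$ub[perm],
                           internal = reactions(net)$internal[perm],
                           massLoss = reactions(net)$massLoss[perm])
  expect_equal(objectiveValue(solveFBA(net2, obj, fixed = list(r0 = 1))),
               opt, tolerance = 1e-8)
})

test_that("duplicating a mass-balance row leaves the optimum unchanged", {
  net <- toyNetwork()
  obj <- fluxObjective("linear", c(r5 = 1))
  opt <- objectiveValue(solveFBA(net, obj, fixed = list(r0 = 1)))
  N2 <- rbind(stoichiometry(net), B2 = stoichiometry(net)["B", ])
  dup <- metabolicNetwork(N2, lb = reactions(net)$lb,
                          ub = reactions(net)$ub,
                          internal = reactions(net)$internal)
  expect_equal(objectiveValue(solveFBA(dup, obj, fixed = list(r0 = 1),
                                       tieBreak = FALSE)),
               opt, tolerance = 1e-8)
})

test_that("the Pareto front connects the single-objective optima monotonically", {
  net <- toyNetwork()
  obj1 <- fluxObjective("linear", c(r5 = 1))
  obj2 <- fluxObjective("totalFlux")
  front <- suppressWarnings(
    paretoFront(net, obj1, obj2, nPoints = 9, fixed = list(r0 = 1)))
  s1 <- solveFBA(net, obj1, fixed = list(r0 = 1))
  s2 <- minimizeTotalFlux(net, fixed = list(r0 = 1))
  expect_equal(front$value1[1], objectiveValue(s1), tolerance = 1e-6)
  expect_equal(front$value2[nrow(front)], objectiveValue(s2),
               tolerance = 1e-6)
  ## as the flux-sum budget shrinks, max r5 cannot increase
  expect_true(all(diff(front$value1) <= 1e-8))
  expect_true(all(diff(front$value2) <= 1e-8))
  ## any sampled feasible point is weakly dominated by some front point
  for (r in randomFeasibleFluxes(net, 5, fixed = list(r0 = 1), seed = 3)) {
    dominated <- any(front$value1 >= r[["r5"]] - 1e-8 &
                       front$value2 <= sum(abs(r)) + 1e-8)
    expect_true(dominated)
  }
})
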