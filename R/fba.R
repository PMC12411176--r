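#' @include AllClasses.R AllGenerics.R lp.R network_core.R
NULL

#' Create a flux objective
#'
#' @param kind `"linear"` (weighted sum of fluxes), `"totalFlux"`
#'   (sum of absolute fluxes, always minimized), or `"growth"`
#'   (mu = w' N r, always maximized unless `sense` says otherwise).
#' @param coefficients named per-reaction weights for `"linear"`.
#' @param sense `"max"` or `"min"`.
#' @return a [FluxObjective-class]
#' @export
fluxObjective <- function(kind = "linear", coefficients = numeric(),
                          sense = if (kind == "totalFlux") "min" else "max") {
  new("FluxObjective", kind = kind, coefficients = coefficients,
      sense = sense)
}

## per-reaction growth coefficients: mu = sum(growthCoef * r)
.growthCoef <- function(net) {
  w <- molecularWeights(net)
  if (anyNA(w)) stop("growth objective requires all molecular weights")
  co <- as.numeric(crossprod(w, net@stoichiometry)) / .MMOL_PER_MOL
  ifelse(net@reactionData$biomass, -co, co)
}

.objCoef <- function(net, obj) {
  rd <- net@reactionData
  switch(obj@kind,
    linear = {
      bad <- setdiff(names(obj@coefficients), rd$id)
      if (length(bad)) stop("objective references unknown reaction(s): ",
                            paste(bad, collapse = ", "))
      co <- setNames(numeric(nrow(rd)), rd$id)
      co[names(obj@coefficients)] <- obj@coefficients
      unname(co)
    },
    growth = .growthCoef(net),
    stop("no linear coefficient form for objective kind ", obj@kind))
}

.evalObjective <- function(net, obj, r) {
  switch(obj@kind,
    totalFlux = sum(abs(r)),
    sum(.objCoef(net, obj) * r))
}

.asSolution <- function(net, res, objValue = res$value) {
  q <- ncol(net@stoichiometry)
  if (res$status != "optimal") {
    return(new("FluxSolution", status = res$status,
               objectiveValue = NA_real_))
  }
  r <- setNames(res$x[seq_len(q)], net@reactionData$id)
  mu <- tryCatch(growthRateFromFluxes(net, r), error = function(e) NA_real_)
  new("FluxSolution", fluxes = r, objectiveValue = objValue,
      status = "optimal", mu = mu)
}

#' Flux balance analysis
#'
#' Solves the linear program max/min g'r subject to N r = 0, flux
#' bounds, and optionally fixed flux values. Degenerate optima are
#' tie-broken by a secondary minimization of the total flux at the
#' optimal objective value, so results are reproducible; the solution
#' carries a `degenerate` attribute when the secondary step changed the
#' flux map.
#'
#' @param net a [MetabolicNetwork-class]
#' @param obj a [FluxObjective-class]
#' @param fixed named list/vector of reaction id -> fixed flux value
#' @param tieBreak run the secondary total-flux minimization?
#' @return a [FluxSolution-class]
#' @export
solveFBA <- function(net, obj, fixed = list(), tieBreak = TRUE) {
  if (obj@kind == "totalFlux")
    return(minimizeTotalFlux(net, fixed = fixed))
  co <- .objCoef(net, obj)
  res <- fluxLP(net, co, maximize = obj@sense == "max", fixed = as.list(fixed))
  sol <- .asSolution(net, res)
  if (sol@status != "optimal" || !tieBreak) return(sol)
  ## secondary lexicographic step: minimal total flux at the optimum
  sec <- .minTotalFluxLP(net, fixed = as.list(fixed),
                         extraEq = list(A = co, b = res$value))
  if (sec$status == "optimal") {
    primary <- sum(abs(sol@fluxes))
    sol2 <- .asSolution(net, sec, objValue = res$value)
    degen <- primary - sum(abs(sol2@fluxes)) > 1e-6
    attr(sol2, "degenerate") <- degen
    return(sol2)
  }
  attr(sol, "degenerate") <- FALSE
  sol
}

## split-variable LP: min sum(p + m) with r = p - m
.minTotalFluxLP <- function(net, fixed = list(), extraEq = NULL,
                            muFloor = NULL) {
  rd <- net@reactionData
  q <- nrow(rd)
  N <- net@stoichiometry[!net@compoundData$external, , drop = FALSE]
  lb <- rd$lb; ub <- rd$ub
  for (id in names(fixed)) {
    j <- match(id, rd$id)
    if (is.na(j)) stop("unknown reaction in 'fixed': ", id)
    lb[j] <- fixed[[id]]; ub[j] <- fixed[[id]]
  }
  Aeq <- cbind(N, -N)
  beq <- rep(0, nrow(N))
  if (!is.null(extraEq)) {
    Aeq <- rbind(Aeq, c(extraEq$A, -extraEq$A))
    beq <- c(beq, extraEq$b)
  }
  ## bounds on r = p - m as inequality rows
  Aub <- rbind(cbind(diag(q), -diag(q)), cbind(-diag(q), diag(q)))
  bub <- c(ub, -lb)
  if (!is.null(muFloor)) {
    g <- .growthCoef(net)
    Aub <- rbind(Aub, c(-g, g))
    bub <- c(bub, -muFloor)
  }
  res <- solveLP(rep(1, 2 * q), Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
                 lb = rep(0, 2 * q), ub = rep(.LP_BIG, 2 * q))
  if (res$status == "optimal") {
    res$x <- res$x[seq_len(q)] - res$x[q + seq_len(q)]
    res$value <- sum(abs(res$x))
  }
  res
}

#' Minimal total flux
#'
#' Minimizes the sum of absolute fluxes via forward/backward variable
#' splitting, subject to steady state, bounds, fixed fluxes, and
#' optionally a growth-rate floor mu = w' N r >= `floorMu`.
#'
#' @inheritParams solveFBA
#' @param floorMu optional growth-rate lower bound, 1/h
#' @return a [FluxSolution-class]; its objective value is sum |r_i|
#' @export
minimizeTotalFlux <- function(net, fixed = list(), floorMu = NULL) {
  res <- .minTotalFluxLP(net, fixed = as.list(fixed), muFloor = floorMu)
  .asSolution(net, res)
}

#' Pareto front over two objectives
#'
#' Epsilon-constraint sweep: objective 2 is constrained on a grid of
#' `nPoints` values between its value at objective 1's optimum and its
#' own optimum, and objective 1 is re-optimized at each grid point.
#' Endpoints therefore equal the two single-objective optima, and the
#' front is non-dominated and monotone. Infeasible grid points are
#' skipped with a warning.
#'
#' @param net a [MetabolicNetwork-class]
#' @param obj1,obj2 [FluxObjective-class] objects (either may be
#'   `totalFlux`)
#' @param nPoints grid size
#' @param fixed named fixed fluxes
#' @return data.frame with `value1`, `value2` and a `solutions`
#'   attribute (list of [FluxSolution-class])
#' @export
paretoFront <- function(net, obj1, obj2, nPoints = 20, fixed = list()) {
  s1 <- solveFBA(net, obj1, fixed = fixed)
  s2 <- solveFBA(net, obj2, fixed = fixed)
  if (s1@status != "optimal" || s2@status != "optimal")
    stop("both objectives must be individually feasible")
  v2.at1 <- .evalObjective(net, obj2, s1@fluxes)
  v2.star <- .evalObjective(net, obj2, s2@fluxes)
  grid <- seq(v2.at1, v2.star, length.out = nPoints)
  rows <- list(); sols <- list()
  for (i in seq_along(grid)) {
    sol <- .solveWithObjectiveCap(net, obj1, obj2, grid[i], fixed)
    if (sol@status != "optimal") {
      warning(sprintf("infeasible grid point %g for objective 2 skipped",
                      grid[i]))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      value1 = .evalObjective(net, obj1, sol@fluxes),
      value2 = .evalObjective(net, obj2, sol@fluxes))
    sols[[length(sols) + 1]] <- sol
  }
  out <- do.call(rbind, rows)
  attr(out, "solutions") <- sols
  out
}

## optimize obj1 subject to obj2 <= / >= cap (in obj2's improving sense).
## Works in split space so totalFlux objectives are linear.
.solveWithObjectiveCap <- function(net, obj1, obj2, cap, fixed = list()) {
  rd <- net@reactionData
  q <- nrow(rd)
  N <- net@stoichiometry[!net@compoundData$external, , drop = FALSE]
  lb <- rd$lb; ub <- rd$ub
  for (id in names(fixed)) {
    j <- match(id, rd$id); lb[j] <- fixed[[id]]; ub[j] <- fixed[[id]]
  }
  splitVec <- function(obj) {
    if (obj@kind == "totalFlux") rep(1, 2 * q)
    else { co <- .objCoef(net, obj); c(co, -co) }
  }
  c1 <- splitVec(obj1); c2 <- splitVec(obj2)
  Aeq <- cbind(N, -N); beq <- rep(0, nrow(N))
  Aub <- rbind(cbind(diag(q), -diag(q)), cbind(-diag(q), diag(q)))
  bub <- c(ub, -lb)
  if (obj2@sense == "min") { Aub <- rbind(Aub, c2); bub <- c(bub, cap) }
  else { Aub <- rbind(Aub, -c2); bub <- c(bub, -cap) }
  res <- solveLP(c1, Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
                 lb = rep(0, 2 * q), ub = rep(.LP_BIG, 2 * q),
                 maximize = obj1@sense == "max")
  if (res$status == "optimal") {
    res$x <- res$x[seq_len(q)] - res$x[q + seq_len(q)]
    res$value <- .evalObjective(net, obj1, res$x)
  }
  .asSolution(net, res)
}
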