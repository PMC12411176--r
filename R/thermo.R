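#' @include AllClasses.R AllGenerics.R lp.R network_core.R fba.R
NULL

#' Construct a thermodynamic specification
#'
#' @param dg0 named standard Gibbs energies (kJ/mol) for the internal
#'   reactions.
#' @param net optional [MetabolicNetwork-class] used to derive default
#'   log-concentration bounds for every compound.
#' @param RT gas constant times temperature, kJ/mol. Default
#'   R = 8.315 J/mol/K at T = 300 K (standard-condition tables use
#'   T = 298 K; T is configurable through this product).
#' @param concMin,concMax default concentration bounds, mmol/gDW, used
#'   where the network carries none.
#' @param xMin,xMax explicit named log-concentration bounds (override).
#' @return a [ThermoSpec-class]
#' @export
thermoSpec <- function(dg0, net = NULL, RT = 8.315e-3 * 300,
                       concMin = 1e-6, concMax = 0.1,
                       xMin = NULL, xMax = NULL) {
  if (is.null(xMin) || is.null(xMax)) {
    if (is.null(net)) stop("either a network or explicit x bounds are needed")
    cd <- net@compoundData
    lo <- ifelse(is.na(cd$concMin), concMin, cd$concMin)
    hi <- ifelse(is.na(cd$concMax), concMax, cd$concMax)
    xMin <- setNames(log(lo), cd$id)
    xMax <- setNames(log(hi), cd$id)
  }
  new("ThermoSpec", dg0 = dg0, RT = RT, xMin = xMin, xMax = xMax)
}

#' Loopless MILP configuration
#'
#' @param bigM magnitude bound on fluxes and Gibbs energies in the
#'   direction-coupled formulation (kJ/mol resp. mmol/gDW/h).
#' @param epsilon strict-inequality margin, kJ/mol.
#' @return a list with `bigM` and `epsilon`
#' @export
looplessConfig <- function(bigM = 1e4, epsilon = 0.1) {
  stopifnot(bigM > epsilon, epsilon > 0)
  list(bigM = bigM, epsilon = epsilon)
}

.internalIds <- function(net) net@reactionData$id[net@reactionData$internal]

.checkDg0 <- function(spec, ids) {
  missing <- setdiff(ids, names(spec@dg0))
  if (length(missing))
    stop("missing dG0' for internal reaction(s): ",
         paste(missing, collapse = ", "))
  spec@dg0[ids]
}

#' Gibbs energies from log-concentrations
#'
#' Evaluates dG = dG0' + RT N'^T x for the internal reactions and the
#' RT-scaled form dG* = dG / RT.
#'
#' @param spec a [ThermoSpec-class]
#' @param net a [MetabolicNetwork-class]
#' @param x named log-concentration vector (x_j = ln c_j, c in mmol/gDW)
#' @return list with `dg` (kJ/mol) and `dgScaled` (dimensionless)
#' @export
scaledDeltaG <- function(spec, net, x) {
  ids <- .internalIds(net)
  dg0 <- .checkDg0(spec, ids)
  Np <- internalStoichiometry(net)
  xv <- setNames(numeric(nrow(Np)), rownames(Np))
  xv[names(x)] <- x
  dg <- dg0 + spec@RT * as.numeric(crossprod(Np, xv))
  names(dg) <- ids
  list(dg = dg, dgScaled = dg / spec@RT)
}

#' Interconvert equilibrium constants and standard Gibbs energies
#'
#' `keqToDg0()` returns dG0' = -RT ln Keq; `dg0ToKeq()` is its inverse.
#' Keq > 1 gives a negative standard value.
#'
#' @param keq equilibrium constant(s), positive
#' @param dg0 standard Gibbs energies, kJ/mol
#' @param RT kJ/mol
#' @return the converted value(s)
#' @export
keqToDg0 <- function(keq, RT = 8.315e-3 * 300) {
  if (any(keq <= 0)) stop("Keq must be positive")
  -RT * log(keq)
}

#' @rdname keqToDg0
#' @export
dg0ToKeq <- function(dg0, RT = 8.315e-3 * 300) exp(-dg0 / RT)

#' Loop-law consistency of standard Gibbs energies
#'
#' Checks K' dG0' = 0 for every cycle basis vector (equivalently the
#' multiplicative equilibrium-constant identity along each cycle).
#'
#' @param spec a [ThermoSpec-class]
#' @param cycles result of [internalCycleBasis()]
#' @param tol absolute tolerance, kJ/mol
#' @return list with per-cycle `values` (K' dG0') and `consistent`
#' @export
checkCycleConsistency <- function(spec, cycles, tol = 1e-6) {
  K <- cycles$basis
  if (!ncol(K))
    return(list(values = numeric(), consistent = TRUE, tol = tol))
  dg0 <- .checkDg0(spec, rownames(K))
  vals <- as.numeric(crossprod(K, dg0))
  list(values = vals, consistent = all(abs(vals) <= tol), tol = tol)
}

#' Sign-vector cycle test
#'
#' A flux sign pattern s_f is loop-free with respect to a cycle sign
#' vector s_c iff |s_c' s_f| < s_c' s_c; equality means the flux runs
#' around the cycle.
#'
#' @param cycleSign,fluxSign sign vectors with entries in -1/0/+1
#' @return list with `lhs`, `rhs` and `passes`
#' @export
signLoopTest <- function(cycleSign, fluxSign) {
  if (length(cycleSign) != length(fluxSign))
    stop("sign vectors must have equal length")
  if (!all(c(cycleSign, fluxSign) %in% c(-1, 0, 1)))
    stop("sign vectors must contain only -1, 0, +1")
  lhs <- abs(sum(cycleSign * fluxSign))
  rhs <- sum(cycleSign * cycleSign)
  list(lhs = lhs, rhs = rhs, passes = lhs < rhs)
}

#' Loopless flux balance analysis
#'
#' Couples each internal flux direction to the sign of its Gibbs energy
#' through a binary variable (z = 1: r >= 0 and dG in [-M, -eps];
#' z = 0: r <= 0 and dG in [eps, M]) and enforces the loop law
#' K' dG = 0 on every cycle basis vector. The mixed-integer program is
#' solved exactly by enumerating the binary assignments of the internal
#' reactions (guard: at most 12) with one LP each.
#'
#' @inheritParams solveFBA
#' @param spec a [ThermoSpec-class] (only the cycle structure and RT
#'   matter; dG0' values are not needed for the direction coupling)
#' @param cfg a [looplessConfig()]
#' @return a [FluxSolution-class] with `deltaG` and `binaries` filled
#' @export
looplessFBA <- function(net, obj, spec = NULL, cfg = looplessConfig(),
                        fixed = list()) {
  rd <- net@reactionData
  q <- nrow(rd)
  intIdx <- which(rd$internal)
  n <- length(intIdx)
  if (n > 12)
    stop("loopless enumeration supports at most 12 internal reactions")
  co <- .objCoef(net, obj)
  K <- internalCycleBasis(net)$basis
  M <- cfg$bigM; eps <- cfg$epsilon
  N <- net@stoichiometry[!net@compoundData$external, , drop = FALSE]
  lb <- rd$lb; ub <- rd$ub
  for (id in names(fixed)) {
    j <- match(id, rd$id); lb[j] <- fixed[[id]]; ub[j] <- fixed[[id]]
  }
  best <- NULL
  grid <- expand.grid(rep(list(c(0, 1)), n))
  for (g in seq_len(nrow(grid))) {
    z <- as.numeric(grid[g, ])
    lbz <- lb; ubz <- ub
    dgLb <- dgUb <- numeric(n)
    skip <- FALSE
    for (k in seq_len(n)) {
      j <- intIdx[k]
      if (z[k] == 1) {
        lbz[j] <- max(lbz[j], 0); ubz[j] <- min(ubz[j], M)
        dgLb[k] <- -M; dgUb[k] <- -eps
      } else {
        lbz[j] <- max(lbz[j], -M); ubz[j] <- min(ubz[j], 0)
        dgLb[k] <- eps; dgUb[k] <- M
      }
      if (lbz[j] > ubz[j]) { skip <- TRUE; break }
    }
    if (skip) next
    Aeq <- cbind(N, matrix(0, nrow(N), n))
    beq <- rep(0, nrow(N))
    if (ncol(K)) {
      Aeq <- rbind(Aeq, cbind(matrix(0, ncol(K), q), t(K)))
      beq <- c(beq, rep(0, ncol(K)))
    }
    res <- solveLP(c(co, numeric(n)), Aeq = Aeq, beq = beq,
                   lb = c(lbz, dgLb), ub = c(ubz, dgUb),
                   maximize = obj@sense == "max")
    if (res$status != "optimal") next
    if (is.null(best) ||
        (obj@sense == "max" && res$value > best$value + 1e-9) ||
        (obj@sense == "min" && res$value < best$value - 1e-9)) {
      best <- res; best$z <- z
    }
  }
  if (is.null(best))
    return(new("FluxSolution", status = "infeasible"))
  ## secondary step: smallest Gibbs magnitudes at the optimal objective
  ## (the sign of each dG is fixed by z, so sum |dG| is linear)
  z <- best$z
  lbz <- lb; ubz <- ub
  dgLb <- dgUb <- numeric(n)
  for (k in seq_len(n)) {
    j <- intIdx[k]
    if (z[k] == 1) {
      lbz[j] <- max(lbz[j], 0); ubz[j] <- min(ubz[j], M)
      dgLb[k] <- -M; dgUb[k] <- -eps
    } else {
      lbz[j] <- max(lbz[j], -M); ubz[j] <- min(ubz[j], 0)
      dgLb[k] <- eps; dgUb[k] <- M
    }
  }
  Aeq <- cbind(N, matrix(0, nrow(N), n))
  beq <- rep(0, nrow(N))
  if (ncol(K)) {
    Aeq <- rbind(Aeq, cbind(matrix(0, ncol(K), q), t(K)))
    beq <- c(beq, rep(0, ncol(K)))
  }
  Aeq <- rbind(Aeq, c(co, numeric(n)))
  beq <- c(beq, best$value)
  sec <- solveLP(c(numeric(q), ifelse(z == 1, -1, 1)),
                 Aeq = Aeq, beq = beq,
                 lb = c(lbz, dgLb), ub = c(ubz, dgUb))
  if (sec$status == "optimal") { sec$z <- z; sec$value <- best$value
    best <- sec }
  sol <- .asSolution(net, best)
  sol@deltaG <- setNames(best$x[q + seq_len(n)], rd$id[intIdx])
  sol@binaries <- setNames(best$z, rd$id[intIdx])
  carrying <- abs(sol@fluxes[rd$id[intIdx]]) > 1e-9
  if (any(abs(sol@deltaG)[carrying] >= M - 1e-6))
    warning("a Gibbs energy of a flux-carrying reaction reached the big-M ",
            "bound; consider raising bigM")
  sol
}

.signsOf <- function(x, tol = 1e-9) {
  s <- sign(x); s[abs(x) <= tol] <- 0; s
}

#' Thermodynamic FBA with explicit concentrations
#'
#' Re-solves the flux program with the direction pattern of a prior
#' flux map imposed, then searches log-concentrations x satisfying
#' sign(r_i) (dG0'_i + RT (N'^T x)_i) <= -epsilon for every running
#' internal reaction, within the concentration bounds. A direction
#' pattern that runs around a cycle admits no such x and is reported
#' infeasible, together with the violated cycle(s).
#'
#' @inheritParams solveFBA
#' @param spec a [ThermoSpec-class] with dG0' for the internal reactions
#' @param signs named sign vector (-1/0/+1) over internal reactions,
#'   typically `sign(fluxes(prior)[internal])`
#' @param epsilon strict-inequality margin, kJ/mol
#' @return a [FluxSolution-class] with `logConc` and `deltaG` filled
#' @export
tfbaWithConcentrations <- function(net, obj, spec, signs, epsilon = 0.1) {
  ids <- .internalIds(net)
  signs <- signs[ids]
  xres <- .solveConcentrationSystem(net, spec, signs, epsilon,
                                    optimizeMargin = FALSE)
  if (!xres$feasible) {
    sol <- new("FluxSolution", status = "infeasible")
    attr(sol, "violatedCycles") <- xres$violated
    return(sol)
  }
  ## direction-constrained flux LP
  fixedDir <- list()
  rd <- net@reactionData
  lb <- setNames(rd$lb, rd$id); ub <- setNames(rd$ub, rd$id)
  for (id in ids) {
    if (signs[id] > 0) lb[id] <- max(lb[id], 0)
    else if (signs[id] < 0) ub[id] <- min(ub[id], 0)
    else { lb[id] <- 0; ub[id] <- 0 }
  }
  net2 <- net
  net2@reactionData$lb <- unname(lb)
  net2@reactionData$ub <- unname(ub)
  sol <- solveFBA(net2, obj)
  if (sol@status != "optimal") return(sol)
  dg <- scaledDeltaG(spec, net, xres$x)$dg
  sol@logConc <- xres$x
  sol@deltaG <- dg
  sol
}

## LP for x: maximize the margin t with sign_i * dG_i <= -t for all
## running internal reactions; feasible iff t* >= epsilon.
.solveConcentrationSystem <- function(net, spec, signs, epsilon,
                                      optimizeMargin = TRUE) {
  ids <- .internalIds(net)
  dg0 <- .checkDg0(spec, ids)
  Np <- internalStoichiometry(net)
  l <- nrow(Np)
  run <- which(signs != 0)
  xMin <- spec@xMin[rownames(Np)]; xMax <- spec@xMax[rownames(Np)]
  if (!length(run)) {
    return(list(feasible = TRUE, x = setNames((xMin + xMax) / 2, rownames(Np)),
                margin = Inf, violated = character()))
  }
  ## rows: sign_i * (dg0_i + RT Np^T x)_i + t <= 0 over running reactions
  A <- t(Np[, run, drop = FALSE]) * spec@RT * signs[run]
  if (optimizeMargin) {
    Aub <- cbind(A, 1)
    bub <- -signs[run] * dg0[run]
    res <- solveLP(c(numeric(l), 1), Aub = Aub, bub = bub,
                   lb = c(xMin, -.LP_BIG), ub = c(xMax, .LP_BIG),
                   maximize = TRUE)
  } else {
    ## feasibility witness at the fixed margin epsilon
    res <- solveLP(numeric(l), Aub = A, bub = -signs[run] * dg0[run] - epsilon,
                   lb = xMin, ub = xMax)
    if (res$status == "optimal") {
      res$x <- c(res$x, 0)
      res$value <- min(-signs[run] *
                         (dg0[run] + spec@RT *
                            as.numeric(crossprod(Np[, run, drop = FALSE],
                                                 res$x[seq_len(l)]))))
    }
  }
  feasible <- res$status == "optimal" && res$value >= epsilon - 1e-9
  violated <- character()
  if (!feasible) {
    K <- internalCycleBasis(net)$basis
    if (ncol(K)) for (k in seq_len(ncol(K))) {
      sc <- .signsOf(K[, k])
      st <- signLoopTest(sc, unname(signs[rownames(K)]))
      if (!st$passes) violated <- c(violated, sprintf("cycle %d", k))
    }
  }
  x <- if (res$status == "optimal") setNames(res$x[seq_len(l)], rownames(Np))
       else setNames(rep(NA_real_, l), rownames(Np))
  list(feasible = feasible, x = x,
       margin = if (res$status == "optimal") res$value else -Inf,
       violated = violated)
}

#' Max-min driving force
#'
#' For a given internal direction pattern, finds log-concentrations
#' maximizing the smallest driving force -sign(r_i) dG_i over the
#' running internal reactions: max B subject to
#' -sign(r_i)(dG0'_i + RT (N'^T x)_i) >= B and the concentration
#' bounds.
#'
#' @inheritParams tfbaWithConcentrations
#' @return list with `B` (kJ/mol), `x` (witness log-concentrations),
#'   `dg` (per-reaction Gibbs energies), `status`
#' @export
mdf <- function(net, spec, signs) {
  ids <- .internalIds(net)
  signs <- signs[ids]
  res <- .solveConcentrationSystem(net, spec, signs, epsilon = 1e-6)
  dg <- if (all(is.finite(res$x))) scaledDeltaG(spec, net, res$x)$dg else NULL
  if (!res$feasible)
    return(list(B = res$margin, x = res$x, dg = dg, status = "infeasible",
                violatedCycles = res$violated))
  list(B = res$margin, x = res$x, dg = dg, status = "optimal")
}
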