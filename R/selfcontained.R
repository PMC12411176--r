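#' @include AllClasses.R AllGenerics.R fixtures.R kinetics.R macro_units.R efm.R
NULL

#' Assemble a self-contained cell model
#'
#' Combines a network carrying kinetic rate laws for its metabolic
#' reactions with a macromolecular unit layer, an enzyme pool bound and
#' a metabolite mass budget. The unit with `metabolite` gating acts as
#' the synthesis machinery: its gated kinetic capacity
#' k_syn (M/K_M) B must cover the synthesis demand of the proteome-like
#' mass (the fixed metabolic unit, the enzymes and itself); the inert
#' remainder unit closes the mass balance.
#'
#' @param network a [MetabolicNetwork-class] with kinetics
#' @param unitModel a [UnitModel-class]; exactly one unit must use
#'   `metabolite` gating, and one `none`-gated unit acts as inert
#'   remainder (the last one)
#' @param eTotal enzyme pool bound, mmol/gDW
#' @param cTotal metabolite mass budget, g/g (default: the unit model's
#'   budget)
#' @param enzymeMW molecular weight used to convert enzyme moles to
#'   mass, g/mol (monomer weight by default)
#' @param concFloor smallest admissible metabolite concentration,
#'   mmol/gDW
#' @return a [SelfContainedModel-class]
#' @export
selfContainedModel <- function(network, unitModel, eTotal,
                               cTotal = unitModel@metaboliteBudget,
                               enzymeMW = 150, concFloor = 1e-6) {
  new("SelfContainedModel", network = network, unitModel = unitModel,
      eTotal = eTotal, cTotal = cTotal, enzymeMW = enzymeMW,
      concFloor = concFloor)
}

#' The toy self-contained model
#'
#' The three-unit fixture network equipped with reversible rate laws
#' for the metabolic reactions (loop-consistent equilibrium constants
#' Keq2 Keq3^2 = Keq4), an irreversible uptake reaction driven by the
#' external substrate, and irreversible export reactions.
#'
#' @param eTotal enzyme pool, mmol/gDW
#' @param kcat turnover number shared by all reactions, 1/h
#' @param K binding constant shared by all internal couplings, mmol/gDW
#' @return a [SelfContainedModel-class]
#' @export
selfContainedToyModel <- function(eTotal = 1e-5, kcat = 1.8e6, K = 0.2) {
  fx <- unitNetwork("three-unit")
  net <- fx$network
  net@kinetics <- list(
    r0 = kineticLaw(kcat, Km = 1),   # MM in the external substrate
    r1 = kineticLaw(kcat, Ks = c(A = K), orderS = c(A = 2),
                    Kp = c(B = K, C = K), orderP = c(B = 1, C = 2),
                    Keq = 10),
    r2 = kineticLaw(kcat, Ks = c(B = K), orderS = c(B = 2),
                    Kp = c(D = K), Keq = 2),
    r3 = kineticLaw(kcat, Ks = c(C = K), Kp = c(B = K), Keq = 3),
    r4 = kineticLaw(kcat, Ks = c(C = K), orderS = c(C = 2),
                    Kp = c(D = K), Keq = 18),
    r5 = kineticLaw(kcat, Ks = c(D = K)),
    r6 = kineticLaw(kcat, Ks = c(A = K), orderS = c(A = 2)))
  selfContainedModel(net, fx$unitModel, eTotal = eTotal)
}

## ---- kinetic flux evaluation ---------------------------------------------

.kineticFluxes <- function(model, E, conc, Sext) {
  net <- model@network
  laws <- net@kinetics
  r <- setNames(numeric(length(laws)), names(laws))
  for (id in names(laws)) {
    law <- laws[[id]]
    e <- if (id %in% names(E)) E[[id]] else 0
    if (!length(law@Ks)) {               # uptake: MM in external substrate
      r[id] <- mmRate(law, e, Sext)
    } else {
      S <- conc[names(law@Ks)]
      P <- if (length(law@Kp)) conc[names(law@Kp)] else numeric()
      r[id] <- reversibleRate(law, e, S, P)
    }
  }
  r
}

## ---- inner steady state ---------------------------------------------------

## unknown vector y = (x_1..x_l (log conc of metabolites), mu, B2)
.scSystem <- function(model, y, E, Sext) {
  net <- model@network
  um <- model@unitModel
  cd <- net@compoundData
  unitIds <- um@units$id
  metIds <- setdiff(cd$id[!cd$external], unitIds)
  l <- length(metIds)
  x <- unname(y[seq_len(l)]); mu <- unname(y[l + 1]); B2 <- unname(y[l + 2])
  conc <- setNames(exp(x), metIds)
  r <- .kineticFluxes(model, E, conc, Sext)
  w <- setNames(cd$mw, cd$id)[metIds]
  eMass <- sum(E) * model@enzymeMW / .MMOL_PER_MOL
  gi <- which(um@units$gating == "metabolite")
  B1 <- um@units$massFraction[[1]]
  B3 <- 1 - model@cTotal - B1 - eMass - B2
  rsyn <- setNames(numeric(length(unitIds)), unitIds)
  rsyn[unitIds[1]] <- mu * (B1 + eMass)
  rsyn[unitIds[gi]] <- mu * B2
  rsyn[unitIds[length(unitIds)]] <- mu * B3
  ## metabolite balances: production - unit drains - dilution
  N <- net@stoichiometry[metIds, names(r), drop = FALSE]
  prod <- as.numeric(N %*% r)
  drain <- numeric(l)
  for (u in unitIds) {
    mono <- um@monomerStoich[[u]]
    drain <- drain + rsyn[[u]] * as.numeric(mono[metIds])
  }
  f <- prod - drain - mu * conc
  budget <- sum(conc * w) / .MMOL_PER_MOL - model@cTotal
  gate <- um@units[gi, ]
  fM <- conc[[gate$gatingCompound]] / gate$Km
  capacity <- gate$kSyn * fM * B2 - mu * (B1 + eMass + B2)
  list(f = c(f, budget, capacity), conc = conc, r = r, mu = mu,
       B = c(B1 = B1, B2 = B2, B3 = B3), eMass = eMass, rsyn = rsyn)
}

## damped Newton with numerical Jacobian on the inner system
.scNewton <- function(model, E, Sext, y0, maxit = 60, tol = 1e-10) {
  fval <- function(y) .scSystem(model, y, E, Sext)$f
  y <- y0
  f <- fval(y)
  n <- length(y)
  for (it in seq_len(maxit)) {
    nf <- sqrt(sum(f^2))
    if (!is.finite(nf)) return(NULL)
    if (nf < tol) break
    J <- matrix(0, n, n)
    h <- pmax(1e-7, abs(y) * 1e-7)
    for (k in seq_len(n)) {
      yk <- y; yk[k] <- yk[k] + h[k]
      J[, k] <- (fval(yk) - f) / h[k]
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      y2 <- y + lam * step
      f2 <- fval(y2)
      if (all(is.finite(f2)) && sqrt(sum(f2^2)) < nf * (1 - 0.25 * lam)) {
        y <- y2; f <- f2; break
      }
      lam <- lam / 2
      if (lam < 1e-8) return(NULL)
    }
  }
  if (sqrt(sum(f^2)) >= 1e-7) return(NULL)
  y
}

.scInitialGuess <- function(model) {
  net <- model@network
  um <- model@unitModel
  cd <- net@compoundData
  unitIds <- um@units$id
  metIds <- setdiff(cd$id[!cd$external], unitIds)
  w <- setNames(cd$mw, cd$id)[metIds]
  fr <- um@monomerStoich[[1]][metIds] * w  # proportional to composition mass
  fr <- fr / sum(fr)
  c0 <- model@cTotal * fr * .MMOL_PER_MOL / w
  c(log(c0), 0.5, 0.05)
}

.scEvaluate <- function(model, E, Sext, y0 = NULL) {
  guesses <- if (!is.null(y0)) list(y0) else {
    base <- .scInitialGuess(model)
    lapply(c(0.5, 0.1, 1.5), function(mu0) { g <- base
      g[length(g) - 1] <- mu0; g })
  }
  for (g in guesses) {
    y <- .scNewton(model, E, Sext, g)
    if (is.null(y)) next
    st <- .scSystem(model, y, E, Sext)
    st$y <- y
    st$feasible <- st$mu > 0 && st$B[["B2"]] > 0 && st$B[["B3"]] >= 0 &&
      all(st$conc >= model@concFloor)
    if (st$feasible) return(st)
    best <- st
  }
  if (exists("best", inherits = FALSE)) best else NULL
}

.softmaxAlloc <- function(theta, eTotal) {
  nE <- length(theta) - 1
  u <- 1 / (1 + exp(-theta[nE + 1]))
  z <- exp(theta[seq_len(nE)] - max(theta[seq_len(nE)]))
  eTotal * u * z / sum(z)
}

## ---- the capstone optimizer ----------------------------------------------

#' Maximize growth of a self-contained model
#'
#' Nested optimization: the outer search allocates the enzyme pool
#' across the metabolic reactions (simplex parameterisation with a
#' usage factor, so sum E_i <= E_total holds by construction); for each
#' allocation the inner damped Newton solves the metabolite steady
#' state (log-concentration balances with unit drains and dilution, the
#' metabolite mass budget, and the synthesis-machinery capacity
#' equation), and the growth rate mu = w' N r follows. Multistart over
#' random initial allocations; the best feasible optimum is retained
#' and every accepted state is independently re-verified (kinetic
#' fluxes, steady-state residuals, budgets, mass closure).
#'
#' @param model a [SelfContainedModel-class]
#' @param Sext external substrate concentration (units of the uptake
#'   law's Km)
#' @param starts number of random multistarts
#' @param seed master seed; start seeds derive from it by a counter
#' @param maxit outer iterations per start
#' @return a [FluxSolution-class] with fluxes (metabolic and molar
#'   unit-synthesis), enzymes, log-concentrations and mu; attributes
#'   `state` (mass closure) and `starts` (per-start manifest)
#' @export
solveSelfContained <- function(model, Sext = 10, starts = 17, seed = 1,
                               maxit = 150) {
  net <- model@network
  rxnIds <- names(net@kinetics)
  nE <- length(rxnIds)
  objective <- function(theta) {
    E <- setNames(.softmaxAlloc(theta, model@eTotal), rxnIds)
    st <- .scEvaluate(model, E, Sext)
    if (is.null(st)) return(1e3)              # no steady state found
    if (!st$feasible) {
      ## graded penalty so the search can climb toward feasibility
      pen <- max(0, -st$mu) + 100 * max(0, -st$B[["B2"]]) +
        100 * max(0, -st$B[["B3"]]) +
        100 * max(0, max(model@concFloor - st$conc))
      return(100 + pen)
    }
    -st$mu
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  manifest <- data.frame(start = integer(), seed = integer(),
                         mu = numeric(), feasible = logical())
  best <- NULL; bestTheta <- NULL
  for (s in seq_len(starts)) {
    set.seed(seed + s - 1L)
    theta0 <- c(rnorm(nE, 0, 1), 1)
    opt <- optim(theta0, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit))
    if (opt$value < 1e2) {
      ## each start carries its own polish, so the best-of-starts
      ## objective is non-decreasing in the number of starts
      opt <- optim(opt$par, objective, method = "Nelder-Mead",
                   control = list(maxit = 2L * maxit, reltol = 1e-12))
    }
    mu <- if (opt$value < 1e2) -opt$value else NA_real_
    manifest <- rbind(manifest, data.frame(
      start = s, seed = seed + s - 1L, mu = mu,
      feasible = is.finite(mu)))
    if (is.finite(mu) && (is.null(best) || mu > best)) {
      best <- mu; bestTheta <- opt$par
    }
  }
  if (is.null(best)) {
    sol <- new("FluxSolution", status = "infeasible")
    attr(sol, "starts") <- manifest
    return(sol)
  }
  E <- setNames(.softmaxAlloc(bestTheta, model@eTotal), rxnIds)
  st <- .scEvaluate(model, E, Sext)
  .scAsSolution(model, st, E, manifest)
}

.scAsSolution <- function(model, st, E, manifest = NULL) {
  net <- model@network
  um <- model@unitModel
  unitIds <- um@units$id
  cd <- net@compoundData
  unitMW <- setNames(cd$mw, cd$id)[unitIds]
  rsynMolar <- st$rsyn * .MMOL_PER_MOL / unitMW
  synCols <- vapply(unitIds, function(u)
    colnames(net@stoichiometry)[which(net@stoichiometry[u, ] > 0)][1], "")
  fluxAll <- setNames(numeric(ncol(net@stoichiometry)),
                      colnames(net@stoichiometry))
  fluxAll[names(st$r)] <- st$r
  fluxAll[synCols] <- rsynMolar
  closure <- c(C = model@cTotal, st$B[["B1"]], Emass = st$eMass,
               st$B[["B2"]], st$B[["B3"]])
  names(closure) <- c("C", "B1", "Emass", "B2", "B3")
  sol <- new("FluxSolution", fluxes = fluxAll, objectiveValue = st$mu,
             status = "optimal", mu = st$mu,
             logConc = log(st$conc), enzymes = E)
  attr(sol, "state") <- list(closure = closure, conc = st$conc,
                             rsyn = st$rsyn, residual = st$f)
  attr(sol, "starts") <- manifest
  sol
}

#' Growth and yield over a substrate range
#'
#' Solves the self-contained model for each external substrate level
#' (warm-started along the sweep) and reports growth rate, biomass
#' yield (g biomass per g substrate taken up) and the mass closure.
#'
#' @inheritParams solveSelfContained
#' @param Svalues positive, sorted substrate levels
#' @return data.frame (S, mu, yield, B1, B2, B3, Emass)
#' @export
substrateSweep <- function(model, Svalues, starts = 5, seed = 1,
                           maxit = 120) {
  wS <- 150  # substrate monomer weight, g/mol
  rows <- list()
  for (S in Svalues) {
    sol <- tryCatch(
      solveSelfContained(model, Sext = S, starts = starts, seed = seed,
                         maxit = maxit),
      error = function(e) NULL)
    if (is.null(sol) || sol@status != "optimal") {
      rows[[length(rows) + 1]] <- data.frame(
        S = S, mu = NA_real_, yield = NA_real_, B1 = NA_real_,
        B2 = NA_real_, B3 = NA_real_, Emass = NA_real_)
      next
    }
    cl <- attr(sol, "state")$closure
    uptakeMass <- wS * sol@fluxes[["r0"]] / .MMOL_PER_MOL
    rows[[length(rows) + 1]] <- data.frame(
      S = S, mu = sol@mu, yield = sol@mu / uptakeMass,
      B1 = cl[["B1"]], B2 = cl[["B2"]], B3 = cl[["B3"]],
      Emass = cl[["Emass"]])
  }
  do.call(rbind, rows)
}

#' Supply/demand decomposition of a metabolite node
#'
#' Partitions the steady-state balance of one metabolite into supply
#' fluxes (incoming), demand fluxes (outgoing through metabolic
#' reactions), the biomass drain (outgoing through unit synthesis) and
#' the dilution term mu c; at steady state the four close to zero.
#'
#' @param model a [SelfContainedModel-class]
#' @param sol a [FluxSolution-class] from [solveSelfContained()]
#' @param metabolite compound id
#' @return list with `supply`, `demand` (named flows, mmol/gDW/h),
#'   `biomassDrain`, `dilution`, `balance`
#' @export
supplyDemand <- function(model, sol, metabolite) {
  net <- model@network
  if (!metabolite %in% net@compoundData$id)
    stop("unknown metabolite: ", metabolite)
  unitIds <- model@unitModel@units$id
  synCols <- colnames(net@stoichiometry)[
    colSums(net@stoichiometry[unitIds, , drop = FALSE] > 0) > 0]
  terms <- net@stoichiometry[metabolite, ] * sol@fluxes
  sup <- terms[terms > 1e-12 & !names(terms) %in% synCols]
  dem <- -terms[terms < -1e-12 & !names(terms) %in% synCols]
  drain <- -sum(terms[names(terms) %in% synCols])
  conc <- attr(sol, "state")$conc
  dil <- if (metabolite %in% names(conc)) sol@mu * conc[[metabolite]] else 0
  list(supply = sup, demand = dem, biomassDrain = drain, dilution = dil,
       balance = sum(sup) - sum(dem) - drain - dil)
}

#' Compare flux solutions against the elementary flux modes
#'
#' Enumerates the network's EFMs, scales every mode to each solution's
#' uptake flux, and reports for each solution its growth rate, total
#' flux, and the distance to the nearest mode (Euclidean distance of
#' the direction-normalized flux vectors).
#'
#' @param net a [MetabolicNetwork-class] (for a
#'   [SelfContainedModel-class], pass its network)
#' @param solutions list of [FluxSolution-class] objects
#' @param uptake id of the uptake reaction used for scaling
#' @return data.frame (mu, totalFlux, nearestEFM, distance)
#' @export
compareToEFMs <- function(net, solutions, uptake = "r0") {
  efms <- enumerateEFMs(net)
  M <- efms$modes
  if (!ncol(M)) stop("network has no elementary flux modes")
  unitDir <- function(v) { n <- sqrt(sum(v^2)); if (n == 0) v else v / n }
  rows <- lapply(solutions, function(sol) {
    r <- sol@fluxes[rownames(M)]
    d <- apply(M, 2, function(e) sqrt(sum((unitDir(r) - unitDir(e))^2)))
    data.frame(mu = sol@mu, totalFlux = sum(abs(r)),
               nearestEFM = colnames(M)[which.min(d)],
               distance = min(d))
  })
  do.call(rbind, rows)
}
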