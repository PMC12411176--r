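#' @include AllClasses.R AllGenerics.R lp.R fba.R
NULL

.AVOGADRO <- 6.022e23

#' Enzyme capacity specification
#'
#' @param kcat named turnover numbers, 1/h; the capacity constraint
#'   |r_i| <= kcat_i E_i binds exactly the reactions named here.
#' @param eTotal total enzyme budget, mmol/gDW.
#' @param eMax per-enzyme upper bound, mmol/gDW (scalar or named).
#' @param weights per-enzyme cost weights for [enzymeCostMin()]
#'   (e.g. molecular weights); default 1.
#' @return a list used by the enzyme-constrained solvers
#' @export
enzymeSpec <- function(kcat, eTotal = Inf, eMax = Inf, weights = 1) {
  if (any(kcat <= 0)) stop("kcat must be positive")
  if (eTotal <= 0) stop("eTotal must be positive")
  ids <- names(kcat)
  list(kcat = kcat,
       eTotal = eTotal,
       eMax = setNames(rep_len(eMax, length(ids)), ids),
       weights = setNames(rep_len(weights, length(ids)), ids))
}

## shared LP: variables r (q), p/m splits and E for capacity reactions.
.enzymeLP <- function(net, esp, objR = NULL, objE = NULL, maximize = FALSE,
                      fixed = list(), muFloor = NULL, muFix = NULL) {
  rd <- net@reactionData
  q <- nrow(rd)
  N <- net@stoichiometry[!net@compoundData$external, , drop = FALSE]
  ids <- names(esp$kcat)
  bad <- setdiff(ids, rd$id)
  if (length(bad)) stop("kcat given for unknown reaction(s): ",
                        paste(bad, collapse = ", "))
  cIdx <- match(ids, rd$id)
  nc <- length(cIdx)
  lb <- rd$lb; ub <- rd$ub
  for (id in names(fixed)) {
    j <- match(id, rd$id)
    if (is.na(j)) stop("unknown reaction in 'fixed': ", id)
    lb[j] <- fixed[[id]]; ub[j] <- fixed[[id]]
  }
  ## variable layout: r (q) | p (nc) | m (nc) | E (nc)
  nv <- q + 3 * nc
  Zq <- function(nr) matrix(0, nr, q)
  Aeq <- cbind(N, matrix(0, nrow(N), 3 * nc))
  beq <- rep(0, nrow(N))
  ## r_i - p_i + m_i = 0 on capacity reactions
  S <- matrix(0, nc, q); S[cbind(seq_len(nc), cIdx)] <- 1
  Aeq <- rbind(Aeq, cbind(S, -diag(nc), diag(nc), matrix(0, nc, nc)))
  beq <- c(beq, rep(0, nc))
  ## p + m - kcat E <= 0
  Aub <- cbind(matrix(0, nc, q), diag(nc), diag(nc), -diag(esp$kcat, nc))
  bub <- rep(0, nc)
  ## sum E <= eTotal
  if (is.finite(esp$eTotal)) {
    Aub <- rbind(Aub, c(numeric(q + 2 * nc), rep(1, nc)))
    bub <- c(bub, esp$eTotal)
  }
  g <- NULL
  if (!is.null(muFloor) || !is.null(muFix)) g <- .growthCoef(net)
  if (!is.null(muFloor)) {
    Aub <- rbind(Aub, c(-g, numeric(3 * nc)))
    bub <- c(bub, -muFloor)
  }
  if (!is.null(muFix)) {
    Aeq <- rbind(Aeq, c(g, numeric(3 * nc)))
    beq <- c(beq, muFix)
  }
  obj <- c(if (is.null(objR)) numeric(q) else objR,
           numeric(2 * nc),
           if (is.null(objE)) numeric(nc) else objE)
  lbAll <- c(lb, rep(0, 2 * nc), rep(0, nc))
  ubAll <- c(ub, rep(.LP_BIG, 2 * nc), pmin(esp$eMax, .LP_BIG))
  res <- solveLP(obj, Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
                 lb = lbAll, ub = ubAll, maximize = maximize)
  if (res$status != "optimal")
    return(new("FluxSolution", status = res$status))
  r <- setNames(res$x[seq_len(q)], rd$id)
  E <- setNames(res$x[q + 2 * nc + seq_len(nc)], ids)
  mu <- tryCatch(growthRateFromFluxes(net, r), error = function(e) NA_real_)
  new("FluxSolution", fluxes = r, objectiveValue = res$value,
      status = "optimal", mu = mu, enzymes = E)
}

#' Enzyme-capacity-constrained FBA
#'
#' Adds |r_i| <= kcat_i E_i (via forward/backward flux splitting),
#' 0 <= E_i <= E_max and sum E_i <= E_total to the flux program and
#' optimizes the flux objective.
#'
#' @inheritParams solveFBA
#' @param esp an [enzymeSpec()]
#' @return a [FluxSolution-class] with enzyme levels attached
#' @export
capacityFBA <- function(net, obj, esp, fixed = list()) {
  co <- .objCoef(net, obj)
  .enzymeLP(net, esp, objR = co, maximize = obj@sense == "max",
            fixed = as.list(fixed))
}

#' Enzyme cost minimization
#'
#' Minimizes the weighted enzyme sum sum w_i E_i subject to the
#' capacity constraints and fixed demands (fixed fluxes and/or a fixed
#' growth rate). At the optimum every enzyme carrying flux is tight:
#' |r_i| = kcat_i E_i.
#'
#' @inheritParams capacityFBA
#' @param fixed named fixed fluxes (the demand)
#' @param mu optional growth rate pinned via w' N r = mu
#' @return a [FluxSolution-class]; objective value is sum w_i E_i
#' @export
enzymeCostMin <- function(net, esp, fixed = list(), mu = NULL) {
  .enzymeLP(net, esp, objE = unname(esp$weights), maximize = FALSE,
            fixed = as.list(fixed), muFix = mu)
}

#' Molecules per cell to specific concentration
#'
#' Converts a copy number to mmol/gDW via Avogadro's number and an
#' average single-cell dry mass (default 1e-12 gDW).
#'
#' @param molecules copy number per cell
#' @param cellMass average cell dry mass, gDW
#' @return concentration, mmol/gDW
#' @export
copyNumberToConc <- function(molecules, cellMass = 1e-12) {
  if (any(molecules < 0) || cellMass <= 0)
    stop("molecule count must be >= 0 and cell mass positive")
  molecules / (.AVOGADRO * cellMass) * .MMOL_PER_MOL
}

#' Turnover number from flux and enzyme level
#'
#' kcat = r / c_E, in 1/h for a flux in mmol/gDW/h and an enzyme
#' concentration in mmol/gDW.
#'
#' @param flux mmol/gDW/h
#' @param enzymeConc mmol/gDW, positive
#' @return apparent turnover number, 1/h
#' @export
estimateKcat <- function(flux, enzymeConc) {
  if (any(enzymeConc <= 0)) stop("enzyme concentration must be positive")
  flux / enzymeConc
}
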