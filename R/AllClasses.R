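#' @import methods
#' @importFrom stats optim runif rnorm setNames
#' @importFrom utils head modifyList read.delim write.table
NULL

## Repository-wide unit conventions:
##   fluxes          mmol/gDW/h
##   concentrations  mmol/gDW   (log-concentrations x = ln c)
##   molecular mass  g/mol
##   Gibbs energies  kJ/mol
##   growth rate     1/h
## The g <-> mmol factor 1000 is applied only inside growth-rate
## computations (mu = w' N r / 1000) and in mass-fraction conversions.
.MMOL_PER_MOL <- 1000

#' Stoichiometric network of compounds and reactions
#'
#' The central container of the package: a dense stoichiometric matrix
#' `N` (compounds x reactions, substrates negative) together with
#' per-compound annotation (molecular weight in g/mol, concentration
#' bounds in mmol/gDW, optional biomass mass fraction in g/g) and
#' per-reaction annotation (flux bounds in mmol/gDW/h, internal flag,
#' standard Gibbs energy in kJ/mol, turnover number in 1/h, and a
#' `massLoss` flag for reactions with an implicit by-product sink).
#'
#' @slot stoichiometry numeric matrix, rows = compounds, cols = reactions.
#' @slot compoundData data.frame with columns `id`, `mw`, `external`,
#'   `concMin`, `concMax`, `massFraction`.
#' @slot reactionData data.frame with columns `id`, `lb`, `ub`,
#'   `internal`, `dg0`, `kcat`, `massLoss`, `biomass`.
#' @slot kinetics named list of [KineticLaw-class] objects (may be empty).
#'
#' @export
setClass("MetabolicNetwork",
  representation(
    stoichiometry = "matrix",
    compoundData  = "data.frame",
    reactionData  = "data.frame",
    kinetics      = "list"
  )
)

setValidity("MetabolicNetwork", function(object) {
  msg <- character()
  N <- object@stoichiometry
  cd <- object@compoundData
  rd <- object@reactionData
  if (nrow(N) != nrow(cd))
    msg <- c(msg, "stoichiometry rows must match compoundData rows")
  if (ncol(N) != nrow(rd))
    msg <- c(msg, "stoichiometry columns must match reactionData rows")
  if (anyDuplicated(cd$id)) msg <- c(msg, "duplicated compound ids")
  if (anyDuplicated(rd$id)) msg <- c(msg, "duplicated reaction ids")
  if (!identical(rownames(N), cd$id))
    msg <- c(msg, "stoichiometry rownames must equal compound ids")
  if (!identical(colnames(N), rd$id))
    msg <- c(msg, "stoichiometry colnames must equal reaction ids")
  if (any(!is.na(cd$mw) & cd$mw <= 0))
    msg <- c(msg, "molecular weights must be positive where given")
  if (any(!is.na(cd$concMin) & !is.na(cd$concMax) & cd$concMin > cd$concMax))
    msg <- c(msg, "concMin must not exceed concMax")
  if (any(rd$lb > rd$ub))
    msg <- c(msg, "reaction lower bounds must not exceed upper bounds")
  fr <- cd$massFraction
  if (any(!is.na(fr))) {
    s <- sum(fr, na.rm = TRUE)
    if (any(fr < 0, na.rm = TRUE) || abs(s - 1) > 1e-9)
      msg <- c(msg, sprintf(
        "biomass mass fractions must lie in [0,1] and sum to 1 (got %.12g)", s))
  }
  if (length(msg)) msg else TRUE
})

#' Result of a flux computation
#'
#' Holds a flux vector (mmol/gDW/h) with its objective value and solver
#' status, plus the optional quantities attached by the thermodynamic,
#' enzymatic and growth formulations: log-concentrations `x = ln c`,
#' Gibbs energies (kJ/mol), direction binaries, enzyme levels (mmol/gDW)
#' and the specific growth rate mu (1/h).
#'
#' @export
setClass("FluxSolution",
  representation(
    fluxes         = "numeric",
    objectiveValue = "numeric",
    status         = "character",
    mu             = "numeric",
    logConc        = "numeric",
    deltaG         = "numeric",
    binaries       = "numeric",
    enzymes        = "numeric"
  ),
  prototype(
    fluxes = numeric(), objectiveValue = NA_real_, status = "optimal",
    mu = NA_real_, logConc = numeric(), deltaG = numeric(),
    binaries = numeric(), enzymes = numeric()
  )
)

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be one of optimal/infeasible/unbounded")
  TRUE
})

#' Thermodynamic reaction data
#'
#' Standard Gibbs energies of the internal reactions (kJ/mol), the
#' product RT (kJ/mol; R = 8.315 J/mol/K, default T = 300 K) and the
#' per-compound log-concentration bounds used by the
#' concentration-coupled formulations.
#'
#' @export
setClass("ThermoSpec",
  representation(
    dg0  = "numeric",   # named, per internal reaction, kJ/mol
    RT   = "numeric",   # kJ/mol
    xMin = "numeric",   # named, per compound, ln(mmol/gDW)
    xMax = "numeric"
  )
)

setValidity("ThermoSpec", function(object) {
  msg <- character()
  if (length(object@RT) != 1 || object@RT <= 0)
    msg <- c(msg, "RT must be a single positive number")
  if (length(object@xMin) != length(object@xMax) ||
      !identical(names(object@xMin), names(object@xMax)))
    msg <- c(msg, "xMin and xMax must be aligned named vectors")
  else if (any(object@xMin > object@xMax))
    msg <- c(msg, "xMin must not exceed xMax")
  if (length(msg)) msg else TRUE
})

#' Reversible rate-law parameters
#'
#' Parameters of the generalised reversible rate law
#' r = kcat E (prod s_i^n_i) (1 - Q/Keq) / (prod(1 + s_i^n_i) +
#' prod(1 + p_j^n_j) - 1) with s = S/Ks, p = P/Kp, and of its
#' irreversible Michaelis-Menten special case. When both turnover
#' numbers are given, Keq is tied to them by the Haldane relationship
#' Keq = kcat+ Kp / (kcat- Ks).
#'
#' @export
setClass("KineticLaw",
  representation(
    kcat      = "numeric",  # 1/h, forward capacity
    kcatMinus = "numeric",  # 1/h, optional backward capacity
    Ks        = "numeric",  # named per substrate, mmol/gDW
    Kp        = "numeric",  # named per product, mmol/gDW
    orderS    = "numeric",  # named molecularities of substrates
    orderP    = "numeric",
    Keq       = "numeric",
    Km        = "numeric"   # MM constant, mmol/gDW (MM variant)
  ),
  prototype(kcatMinus = NA_real_, Keq = NA_real_, Km = NA_real_)
)

setValidity("KineticLaw", function(object) {
  msg <- character()
  if (length(object@kcat) != 1 || object@kcat <= 0)
    msg <- c(msg, "kcat must be a single positive number")
  if (any(object@Ks <= 0) || any(object@Kp <= 0))
    msg <- c(msg, "binding constants must be positive")
  ords <- c(object@orderS, object@orderP)
  if (length(ords) && (any(ords <= 0) || any(ords != round(ords))))
    msg <- c(msg, "molecularities must be positive integers")
  if (!is.na(object@kcatMinus) && !is.na(object@Keq) &&
      length(object@Ks) == 1 && length(object@Kp) == 1) {
    hk <- object@kcat * object@Kp / (object@kcatMinus * object@Ks)
    if (abs(hk - object@Keq) > 1e-9 * abs(object@Keq))
      msg <- c(msg, "Keq violates the Haldane relationship kcat+ Kp/(kcat- Ks)")
  }
  if (length(msg)) msg else TRUE
})

#' Macromolecular-unit layer on a network
#'
#' Coarse-grained biomass sectors (protein-, ribosome-, remainder-like
#' units) with mass fractions B_j (g/g), monomer composition (mmol of
#' metabolite monomer per g of unit), synthesis gating and first-order
#' synthesis constants. The metabolite mass budget (default 0.1 g/g) is
#' the share of total cell mass held as free metabolites.
#'
#' @export
setClass("UnitModel",
  representation(
    units            = "data.frame",  # id, massFraction, gating, kSyn, Km
    monomerStoich    = "list",        # unit id -> named mmol monomer per g unit
    metaboliteBudget = "numeric"      # g/g
  )
)

setValidity("UnitModel", function(object) {
  msg <- character()
  u <- object@units
  need <- c("id", "massFraction", "gating", "kSyn", "Km")
  if (!all(need %in% names(u)))
    msg <- c(msg, paste("units must have columns", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(u$id)) msg <- c(msg, "duplicated unit ids")
    if (any(u$massFraction < 0)) msg <- c(msg, "unit mass fractions must be >= 0")
    bad <- setdiff(u$gating, c("none", "self", "metabolite"))
    if (length(bad)) msg <- c(msg, "gating must be none/self/metabolite")
    if (!all(u$id %in% names(object@monomerStoich)))
      msg <- c(msg, "every unit needs a monomer stoichiometry entry")
  }
  if (object@metaboliteBudget < 0 || object@metaboliteBudget >= 1)
    msg <- c(msg, "metabolite budget must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Linear flux objective
#'
#' @slot kind one of `linear`, `totalFlux`, `growth`, `minEnzyme`.
#' @slot coefficients named per-reaction weights (for `linear`).
#' @slot sense `"max"` or `"min"`.
#' @export
setClass("FluxObjective",
  representation(kind = "character", coefficients = "numeric",
                 sense = "character"),
  prototype(kind = "linear", coefficients = numeric(), sense = "max")
)

setValidity("FluxObjective", function(object) {
  if (!object@kind %in% c("linear", "totalFlux", "growth", "minEnzyme"))
    return("kind must be linear/totalFlux/growth/minEnzyme")
  if (!object@sense %in% c("max", "min"))
    return("sense must be max or min")
  TRUE
})

#' Self-contained cell model
#'
#' A metabolic network with kinetic rate laws for every metabolic
#' reaction, a macromolecular unit layer, an enzyme pool bound E_total
#' (mmol/gDW) and a metabolite mass budget C_total (g/g). The mass
#' closure C + sum(B_j) + E_mass = 1 g/g is enforced at solve time.
#'
#' @export
setClass("SelfContainedModel",
  representation(
    network   = "MetabolicNetwork",
    unitModel = "UnitModel",
    eTotal    = "numeric",   # mmol/gDW
    cTotal    = "numeric",   # g/g
    enzymeMW  = "numeric",   # g/mol used to convert enzyme moles to mass
    concFloor = "numeric"    # mmol/gDW, metabolite concentrations cannot be 0
  )
)

setValidity("SelfContainedModel", function(object) {
  msg <- character()
  if (object@eTotal <= 0) msg <- c(msg, "eTotal must be positive")
  if (object@cTotal <= 0 || object@cTotal >= 1)
    msg <- c(msg, "cTotal must lie in (0, 1)")
  met <- !object@network@compoundData$external
  if (!length(object@network@kinetics))
    msg <- c(msg, "kinetic laws are required for a self-contained model")
  if (length(msg)) msg else TRUE
})

## ---- show methods ---------------------------------------------------------

#' @export
setMethod("show", "MetabolicNetwork", function(object) {
  cd <- object@compoundData; rd <- object@reactionData
  cat(sprintf("MetabolicNetwork: %d compounds x %d reactions\n",
              nrow(cd), nrow(rd)))
  cat("  compounds: ", paste(head(cd$id, 8), collapse = ", "),
      if (nrow(cd) > 8) ", ..." else "", "\n", sep = "")
  cat("  reactions: ", paste(head(rd$id, 8), collapse = ", "),
      if (nrow(rd) > 8) ", ..." else "", "\n", sep = "")
  cat(sprintf("  internal: %d, with kinetics: %d, mass-loss sinks: %d\n",
              sum(rd$internal), length(object@kinetics), sum(rd$massLoss)))
  invisible(NULL)
})

#' @export
setMethod("show", "FluxSolution", function(object) {
  cat(sprintf("FluxSolution (%s)", object@status))
  if (!is.na(object@objectiveValue))
    cat(sprintf(", objective = %.6g", object@objectiveValue))
  if (!is.na(object@mu)) cat(sprintf(", mu = %.6g 1/h", object@mu))
  cat("\n")
  if (length(object@fluxes)) {
    f <- object@fluxes
    cat("  fluxes (mmol/gDW/h):\n")
    print(round(f, 6))
  }
  invisible(NULL)
})

#' @export
setMethod("show", "ThermoSpec", function(object) {
  cat(sprintf("ThermoSpec: RT = %.4f kJ/mol, %d reaction dG0', %d compound bounds\n",
              object@RT, length(object@dg0), length(object@xMin)))
  invisible(NULL)
})

#' @export
setMethod("show", "KineticLaw", function(object) {
  cat(sprintf("KineticLaw: kcat = %.4g 1/h", object@kcat))
  if (!is.na(object@Keq)) cat(sprintf(", Keq = %.4g", object@Keq))
  if (!is.na(object@Km)) cat(sprintf(", Km = %.4g (MM)", object@Km))
  cat(sprintf(", %d substrate / %d product binding constants\n",
              length(object@Ks), length(object@Kp)))
  invisible(NULL)
})

#' @export
setMethod("show", "UnitModel", function(object) {
  cat(sprintf("UnitModel: %d units, metabolite budget %.3g g/g\n",
              nrow(object@units), object@metaboliteBudget))
  print(object@units)
  invisible(NULL)
})

#' @export
setMethod("show", "SelfContainedModel", function(object) {
  cat("SelfContainedModel\n")
  cat(sprintf("  enzyme pool E_total = %.4g mmol/gDW, metabolite budget C_total = %.3g g/g\n",
              object@eTotal, object@cTotal))
  show(object@network)
  invisible(NULL)
})
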