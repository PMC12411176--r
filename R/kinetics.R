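#' @include AllClasses.R model_io.R
NULL

#' Irreversible Michaelis-Menten rate
#'
#' r = kcat E S / (S + K_M); bounded by the capacity kcat E.
#'
#' @param law a [KineticLaw-class] with `Km` set
#' @param E enzyme level, mmol/gDW
#' @param S substrate concentration, mmol/gDW
#' @return flux, mmol/gDW/h
#' @export
mmRate <- function(law, E, S) {
  if (any(S < 0) || any(E < 0)) stop("S and E must be non-negative")
  if (is.na(law@Km)) stop("mmRate needs a Michaelis constant Km")
  law@kcat * E * S / (S + law@Km)
}

## Saturation and thermodynamic factors of the reversible law.
## numerator folded so that S = 0 with products present is well defined.
.kineticParts <- function(law, S, P) {
  if (length(S) != length(law@Ks) || length(P) != length(law@Kp))
    stop("S/P must match the law's substrate/product binding constants")
  if (any(S < 0) || any(P < 0)) stop("concentrations must be non-negative")
  s <- S / law@Ks; p <- P / law@Kp
  ns <- law@orderS; np <- law@orderP
  prodS <- prod(s^ns)
  denom <- prod(1 + s^ns) + prod(1 + p^np) - 1
  etaS <- prodS / denom
  Keq <- law@Keq
  if (is.na(Keq) || !is.finite(Keq)) {       # irreversible limit
    etaT <- 1
  } else {
    Q <- prod(P^np) / prod(S^ns)             # mass-action ratio
    etaT <- 1 - Q / Keq
  }
  ## numerator robust at S = 0 (etaS * etaT as a single expression)
  sat <- if (is.na(Keq) || !is.finite(Keq)) prodS else
    prodS - prod(P^np) / (prod(law@Ks^ns) * Keq)
  list(etaS = etaS, etaT = etaT, denom = denom, satThermo = sat / denom)
}

#' Generalised reversible rate law
#'
#' r = kcat E prod(s_i^n_i) (1 - Q/Keq) /
#' (prod(1 + s_i^n_i) + prod(1 + p_j^n_j) - 1), with s = S/Ks,
#' p = P/Kp and Q the mass-action ratio. The sign of r equals the sign
#' of (1 - Q/Keq): the reaction vanishes exactly at equilibrium and is
#' positive whenever the scaled Gibbs energy is negative. With no
#' products and `Keq = NA` the law is the irreversible limit.
#'
#' @param law a [KineticLaw-class]
#' @param E enzyme level, mmol/gDW
#' @param S,P substrate/product concentration vectors, mmol/gDW,
#'   aligned with the law's `Ks`/`Kp`
#' @return flux, mmol/gDW/h (|r| <= kcat E)
#' @export
reversibleRate <- function(law, E, S, P = numeric()) {
  parts <- .kineticParts(law, S, P)
  law@kcat * E * parts$satThermo
}

#' Capacity / saturation / thermodynamic decomposition
#'
#' Splits the reversible rate into eta_c = kcat E (capacity),
#' eta_s in [0, 1] (saturation) and eta_t = 1 - Q/Keq = 1 - exp(dG*)
#' (thermodynamic drive); their product reassembles the rate exactly.
#'
#' @inheritParams reversibleRate
#' @return list with `etaC`, `etaS`, `etaT` and `rate`
#' @export
rateDecomposition <- function(law, E, S, P = numeric()) {
  parts <- .kineticParts(law, S, P)
  etaC <- law@kcat * E
  list(etaC = etaC, etaS = parts$etaS, etaT = parts$etaT,
       rate = etaC * parts$etaS * parts$etaT)
}

#' Haldane relationship
#'
#' Keq = kcat+ K_P / (kcat- K_S): the equilibrium constant implied by a
#' thermodynamically consistent set of kinetic constants.
#'
#' @param kcatPlus,kcatMinus forward/backward turnover numbers, 1/h
#' @param Ks,Kp substrate/product binding constants
#' @return the equilibrium constant
#' @export
haldaneKeq <- function(kcatPlus, kcatMinus, Ks, Kp) {
  if (any(c(kcatPlus, kcatMinus, Ks, Kp) <= 0))
    stop("all Haldane inputs must be positive")
  kcatPlus * Kp / (kcatMinus * Ks)
}

#' Enzyme demand for a target flux
#'
#' Inverts the reversible rate law: E = r / (kcat eta_s eta_t). The
#' demand diverges as the mass-action ratio approaches equilibrium; a
#' target whose direction contradicts the thermodynamic drive is
#' rejected as infeasible.
#'
#' @param law a [KineticLaw-class]
#' @param targetFlux requested flux, mmol/gDW/h (signed)
#' @param S,P concentrations as in [reversibleRate()]
#' @return enzyme level, mmol/gDW
#' @export
enzymeDemand <- function(law, targetFlux, S, P = numeric()) {
  parts <- .kineticParts(law, S, P)
  f <- parts$satThermo
  if (f == 0 || sign(f) != sign(targetFlux))
    stop("thermodynamically infeasible demand: the rate law cannot carry ",
         "a flux of this sign at these concentrations")
  targetFlux / (law@kcat * f)
}
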