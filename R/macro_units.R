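#' @include AllClasses.R AllGenerics.R network_core.R
NULL

#' Biomass drain pseudo-reaction from a gram-basis composition
#'
#' Converts mass fractions (g compound per g biomass) into the molar
#' drain coefficients of the single biomass reaction of standard FBA:
#' coefficient_j = fraction_j / w_j (mol/gDW), so that one unit of the
#' biomass flux (1/h) drains exactly 1 g/gDW of metabolite mass.
#'
#' @param fractions named mass fractions, g/g, summing to 1
#' @param weights named molecular weights, g/mol
#' @return list with `id`, `coefficients` (positive molar drains,
#'   mol/gDW), `stoich` (the signed column, mol/gDW) and `massPerUnit`
#'   (g drained per unit flux; exactly 1)
#' @export
biomassPseudoreaction <- function(fractions, weights) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mass fractions must sum to 1")
  missing <- setdiff(names(fractions), names(weights))
  if (length(missing))
    stop("missing molecular weight for compound(s): ",
         paste(missing, collapse = ", "))
  w <- weights[names(fractions)]
  coef <- fractions / w
  list(id = "biomass", coefficients = coef, stoich = -coef,
       massPerUnit = sum(coef * w))
}

#' Growth-coupled steady-state matrix M = I - c w'
#'
#' The steady state of the concentration balance dc/dt = N r - mu c
#' with mu = w' N r is M N r = 0 where M = I - c w' (outer product;
#' the mmol/g factor is applied so the product c w' is dimensionless).
#' With c = 0, M is the identity and plain FBA is recovered; when the
#' concentrations account for the full cell mass (w'c = 1 g/g), w'M = 0
#' and the growth equation is contained in the steady-state system.
#'
#' @param conc concentration vector, mmol/gDW
#' @param weights molecular weight vector, g/mol, same length
#' @return the l x l matrix M
#' @export
buildMMatrix <- function(conc, weights) {
  if (length(conc) != length(weights))
    stop("conc and weights must have equal length")
  diag(length(conc)) - outer(conc, weights) / .MMOL_PER_MOL
}

#' Steady-state synthesis rates of macromolecular units
#'
#' Units that are only diluted by growth satisfy r_syn,j = mu B_j, so
#' the synthesis rates are proportional to the mass fractions and their
#' ratios to the fractions all equal mu.
#'
#' @param model a [UnitModel-class]
#' @param mu specific growth rate, 1/h
#' @return data.frame with unit id, mass fraction and synthesis mass
#'   flux `rsyn` (g/gDW/h)
#' @export
unitSteadyState <- function(model, mu) {
  if (mu < 0) stop("mu must be non-negative")
  u <- model@units
  data.frame(id = u$id, massFraction = u$massFraction,
             rsyn = mu * u$massFraction, stringsAsFactors = FALSE)
}

#' Allocation scan of the reduced two-unit model
#'
#' The reduced feedback model: unit B1 drives uptake (r0 = k1 B1,
#' mmol/gDW/h) and unit B2 drives its own and B1's synthesis
#' (kinetic capacity k2 B2, g/gDW/h); overflow r1 excretes surplus
#' substrate and mu = wA (r0 - r1) / 1000. For each B1 on a grid over
#' [0, BTotal] the realized steady state is the smaller of the
#' uptake-limited and synthesis-limited growth rates; at the optimum
#' the two branches intersect and the overflow vanishes.
#'
#' @param k1 uptake capacity per unit B1, mmol/gDW/h per g/g
#' @param k2 synthesis capacity per unit B2, 1/h
#' @param BTotal total unit mass, g/g
#' @param grid number of grid points (>= 3)
#' @param wA monomer molecular weight, g/mol
#' @return data.frame (B1, B2, r0, r1, rsyn, mu) with the optimum row
#'   index in attribute `optimum`
#' @export
reducedAllocationScan <- function(k1 = 100, k2 = 1.2, BTotal = 1,
                                  grid = 401, wA = 150) {
  stopifnot(k1 > 0, k2 > 0, grid >= 3)
  B1 <- seq(0, BTotal, length.out = grid)
  B2 <- BTotal - B1
  r0 <- k1 * B1
  muUptake <- wA * r0 / .MMOL_PER_MOL / BTotal      # all uptake to growth
  muSynth <- k2 * B2 / BTotal                       # machinery-limited
  mu <- pmin(muUptake, muSynth)
  rsyn <- mu * BTotal                               # g/gDW/h into units
  r1 <- r0 - .MMOL_PER_MOL * rsyn / wA              # overflow, >= 0
  out <- data.frame(B1 = B1, B2 = B2, r0 = r0, r1 = r1, rsyn = rsyn,
                    mu = mu)
  attr(out, "optimum") <- which.max(mu)
  out
}

#' Scenario sweeps of the reduced allocation model
#'
#' `substrate_limitation` rescales the uptake capacity k1 by each value
#' (a proxy for the external substrate level) and reports the
#' re-optimized allocation; growth saturates hyperbolically because
#' resources must be shared between uptake and synthesis machinery.
#' `heterologous_burden` removes each value from the allocatable unit
#' mass (mimicking heterologous protein production) and re-optimizes.
#'
#' @param scenario `"substrate_limitation"` or `"heterologous_burden"`
#' @param values positive scaling factors resp. burdens (g/g)
#' @inheritParams reducedAllocationScan
#' @return data.frame (value, B1, B2, mu)
#' @export
scenarioSweep <- function(scenario = c("substrate_limitation",
                                       "heterologous_burden"),
                          values, k1 = 100, k2 = 1.2, BTotal = 1,
                          grid = 401, wA = 150) {
  scenario <- match.arg(scenario)
  rows <- lapply(values, function(v) {
    if (scenario == "substrate_limitation") {
      scan <- reducedAllocationScan(k1 * v, k2, BTotal, grid, wA)
      i <- attr(scan, "optimum")
      return(data.frame(value = v, B1 = scan$B1[i], B2 = scan$B2[i],
                        mu = scan$mu[i]))
    }
    ## burden: v g/g of the unit mass is unavailable, but the full
    ## BTotal of biomass (burden included) must still be synthesized
    ## and diluted
    avail <- BTotal - v
    if (avail <= 0)
      return(data.frame(value = v, B1 = NA_real_, B2 = NA_real_, mu = 0))
    B1 <- seq(0, avail, length.out = grid)
    mu <- pmin(wA * k1 * B1 / .MMOL_PER_MOL, k2 * (avail - B1)) / BTotal
    i <- which.max(mu)
    data.frame(value = v, B1 = B1[i], B2 = avail - B1[i], mu = mu[i])
  })
  do.call(rbind, rows)
}
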