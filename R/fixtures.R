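#' @include AllClasses.R model_io.R
NULL

## Molecular weights of the four toy metabolites, g/mol. They are the
## ratios of the biomass composition on the gram basis (0.35, 0.15, 0.3,
## 0.2 g/g) to its molar coefficients, kept as exact fractions
## (e.g. 0.35 / (7/3000) = 150).
.TOY_MW <- c(A = 150, B = 100, C = 100, D = 200)
.TOY_FRACTIONS <- c(A = 0.35, B = 0.15, C = 0.3, D = 0.2)

#' The four-metabolite toy network
#'
#' Builds the 4 x 7 network (compounds A-D; input `r0`, internal
#' `r1`-`r4` of which `r2`,`r3`,`r4` form a cycle, exchange `r5`,`r6`).
#' `r6` (2A -> D) is not mass balanced as written: 100 g/mol leave as an
#' implicit excreted by-product, so it carries the `massLoss` flag.
#' With `biomass = TRUE` the biomass composition (0.35/0.15/0.3/0.2 g/g
#' over A-D) is attached together with its drain column `rbio`
#' (coefficients in mmol/gDW so that a flux of 1 1/h drains 1 g/gDW of
#' metabolite mass).
#'
#' @param biomass attach biomass composition and drain column?
#' @return a [MetabolicNetwork-class]
#' @export
toyNetwork <- function(biomass = FALSE) {
  N <- matrix(c(
    1, -2,  0,  0,  0,  0, -2,
    0,  1, -2,  1,  0,  0,  0,
    0,  2,  0, -1, -2,  0,  0,
    0,  0,  1,  0,  1, -1,  1), 4, 7, byrow = TRUE,
    dimnames = list(c("A", "B", "C", "D"),
                    c("r0", "r1", "r2", "r3", "r4", "r5", "r6")))
  internal <- c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  lb <- ifelse(internal, -1000, 0)
  ub <- rep(1000, 7)
  massLoss <- c(rep(FALSE, 6), TRUE)
  if (!biomass) {
    return(metabolicNetwork(N, mw = .TOY_MW, lb = lb, ub = ub,
                            internal = internal, massLoss = massLoss))
  }
  bio <- -1000 * .TOY_FRACTIONS / .TOY_MW   # mmol/gDW per unit (1/h) flux
  N2 <- cbind(N, rbio = bio)
  metabolicNetwork(
    N2, mw = .TOY_MW,
    lb = c(lb, 0), ub = c(ub, 1000),
    internal = c(internal, FALSE),
    massLoss = c(massLoss, FALSE),
    biomass = c(rep(FALSE, 7), TRUE),
    massFraction = .TOY_FRACTIONS)
}

#' The internal sub-network of the toy model
#'
#' The 4 x 4 matrix of the internal reactions `r1`-`r4`; its
#' one-dimensional null space is the thermodynamic cycle built by
#' `r2`, `r3`, `r4`.
#'
#' @return a [MetabolicNetwork-class] with all reactions internal
#' @export
internalNetwork <- function() {
  N <- matrix(c(
    -2,  0,  0,  0,
     1, -2,  1,  0,
     2,  0, -1, -2,
     0,  1,  0,  1), 4, 4, byrow = TRUE,
    dimnames = list(c("A", "B", "C", "D"), c("r1", "r2", "r3", "r4")))
  metabolicNetwork(N, mw = .TOY_MW, internal = TRUE)
}

#' Construct a macromolecular unit model
#'
#' @param units data.frame with columns `id`, `massFraction` (g/g),
#'   `gating` (`"none"`, `"self"` or `"metabolite"`), `kSyn` (1/h) and
#'   `Km` (mmol/gDW; used by the `f_M = M/K_M` gating).
#' @param monomerStoich named list: unit id -> named vector of mmol of
#'   metabolite monomer consumed per g of unit synthesised.
#' @param metaboliteBudget free-metabolite mass budget, g/g.
#' @return a [UnitModel-class]
#' @export
unitModel <- function(units, monomerStoich, metaboliteBudget = 0.1) {
  if (is.null(units$gatingCompound))
    units$gatingCompound <- NA_character_
  new("UnitModel", units = units, monomerStoich = monomerStoich,
      metaboliteBudget = metaboliteBudget)
}

#' Networks with macromolecular units
#'
#' Three fixture variants of increasing size:
#' \describe{
#'   \item{`two-unit`}{one metabolite A with input `r0` and overflow
#'     `r1`, plus synthesis of units B1 and B2 consuming `gamma2` resp.
#'     `gamma3` mol of A per mol of unit. Unit weights follow
#'     `w = (wA, gamma2 wA, gamma3 wA)`.}
#'   \item{`two-unit-massfrac`}{the same network written on the
#'     mass-fraction basis (mol/g coefficients), whose growth-mode null
#'     space entries for the synthesis rates are all 1.}
#'   \item{`three-unit`}{the toy network plus molar drains into units
#'     B1, B2, B3, each with the biomass monomer composition; all unit
#'     synthesis columns conserve mass exactly.}
#' }
#'
#' @param variant fixture name.
#' @param gamma2,gamma3 monomers per unit for the two-unit variants.
#' @param fB1 mass fraction of B1 for `two-unit-massfrac`.
#' @param unitMW polymer molecular weight for `three-unit`, g/mol.
#' @return `list(network = MetabolicNetwork, unitModel = UnitModel)`
#' @export
unitNetwork <- function(variant = c("two-unit", "two-unit-massfrac",
                                    "three-unit"),
                        gamma2 = 100, gamma3 = 200, fB1 = 0.5,
                        unitMW = 10000) {
  variant <- tryCatch(match.arg(variant), error = function(e)
    stop("unknown variant; choose one of ",
         "'two-unit', 'two-unit-massfrac', 'three-unit'", call. = FALSE))
  wA <- .TOY_MW[["A"]]
  if (variant == "two-unit") {
    N <- matrix(c(
      1, -1, -gamma2, -gamma3,
      0,  0,  1,       0,
      0,  0,  0,       1), 3, 4, byrow = TRUE,
      dimnames = list(c("A", "B1", "B2"), c("r0", "r1", "r2", "r3")))
    net <- metabolicNetwork(
      N, mw = c(A = wA, B1 = gamma2 * wA, B2 = gamma3 * wA),
      external = c(A = FALSE, B1 = TRUE, B2 = TRUE),
      lb = 0, ub = 1000,
      internal = c(FALSE, FALSE, TRUE, TRUE))
    um <- unitModel(
      data.frame(id = c("B1", "B2"), massFraction = c(0.5, 0.5),
                 gating = "none", kSyn = NA_real_, Km = NA_real_,
                 stringsAsFactors = FALSE),
      monomerStoich = list(B1 = c(A = 1000 / wA), B2 = c(A = 1000 / wA)),
      metaboliteBudget = 0)
    return(list(network = net, unitModel = um))
  }
  if (variant == "two-unit-massfrac") {
    fB2 <- 1 - fB1
    ## mol/g coefficients exactly as the mass-fraction formulation prints
    ## them; synthesis fluxes are on the 1/h growth scale.
    N <- matrix(c(
      1, -1, -fB1 / wA, -fB2 / wA,
      0,  0,  fB1 / (gamma2 * wA), 0,
      0,  0,  0, fB2 / (gamma3 * wA)), 3, 4, byrow = TRUE,
      dimnames = list(c("A", "B1", "B2"), c("r0", "r1", "s1", "s2")))
    net <- metabolicNetwork(
      N, mw = c(A = wA, B1 = gamma2 * wA, B2 = gamma3 * wA),
      external = c(A = FALSE, B1 = TRUE, B2 = TRUE),
      lb = 0, ub = 1000,
      internal = c(FALSE, FALSE, TRUE, TRUE))
    um <- unitModel(
      data.frame(id = c("B1", "B2"), massFraction = c(fB1, fB2),
                 gating = "none", kSyn = NA_real_, Km = NA_real_,
                 stringsAsFactors = FALSE),
      monomerStoich = list(B1 = c(A = 1000 / wA), B2 = c(A = 1000 / wA)),
      metaboliteBudget = 0)
    return(list(network = net, unitModel = um))
  }
  ## three-unit: toy network + molar unit-synthesis drains
  toy <- toyNetwork()
  N <- stoichiometry(toy)
  mono <- 1000 * unitMW * .TOY_FRACTIONS / .TOY_MW / 1000  # mmol monomer/mmol unit
  l <- nrow(N)
  Nu <- rbind(cbind(N, s1 = 0, s2 = 0, s3 = 0),
              B1 = c(rep(0, 7), 1, 0, 0),
              B2 = c(rep(0, 7), 0, 1, 0),
              B3 = c(rep(0, 7), 0, 0, 1))
  for (s in c("s1", "s2", "s3")) Nu[names(mono), s] <- -mono
  rd <- reactions(toy)
  net <- metabolicNetwork(
    Nu,
    mw = c(.TOY_MW, B1 = unitMW, B2 = unitMW, B3 = unitMW),
    external = c(A = FALSE, B = FALSE, C = FALSE, D = FALSE,
                 B1 = TRUE, B2 = TRUE, B3 = TRUE),
    lb = c(rd$lb, 0, 0, 0), ub = c(rd$ub, 1000, 1000, 1000),
    internal = c(rd$internal, FALSE, FALSE, FALSE),
    massLoss = c(rd$massLoss, FALSE, FALSE, FALSE))
  perg <- 1000 * .TOY_FRACTIONS / .TOY_MW   # mmol monomer per g unit
  um <- unitModel(
    data.frame(id = c("B1", "B2", "B3"),
               massFraction = c(0.3, 0.2, 0.4),
               gating = c("none", "metabolite", "none"),
               kSyn = c(NA_real_, 20, NA_real_),
               Km = c(NA_real_, 0.5, NA_real_),
               gatingCompound = c(NA_character_, "A", NA_character_),
               stringsAsFactors = FALSE),
    monomerStoich = list(B1 = perg, B2 = perg, B3 = perg),
    metaboliteBudget = 0.1)
  list(network = net, unitModel = um)
}

#' Random mass-conservative network
#'
#' Samples positive molecular weights and builds `q` internal reaction
#' columns whose last nonzero coefficient is solved from the others so
#' that `w' n = 0` holds exactly. Deterministic for a fixed seed; the
#' global RNG state is left untouched.
#'
#' @param l number of compounds (>= 2)
#' @param q number of reactions (>= 1)
#' @param seed integer seed
#' @return a [MetabolicNetwork-class] with all reactions internal
#' @export
randomConservativeNetwork <- function(l, q, seed) {
  stopifnot(l >= 2, q >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  w <- runif(l, 50, 300)
  cids <- sprintf("m%d", seq_len(l))
  rids <- sprintf("v%d", seq_len(q))
  N <- matrix(0, l, q, dimnames = list(cids, rids))
  for (k in seq_len(q)) {
    nPart <- if (l == 2) 2L else sample(2:l, 1)
    idx <- sort(sample(l, nPart))
    coef <- round(runif(nPart - 1, -3, 3), 2)
    if (all(coef == 0)) coef[1] <- 1
    last <- -sum(coef * w[idx[-nPart]]) / w[idx[nPart]]
    N[idx, k] <- c(coef, last)
  }
  metabolicNetwork(N, mw = setNames(w, cids), internal = TRUE)
}
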