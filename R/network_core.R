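#' @include AllClasses.R AllGenerics.R
NULL

#' Audit mass conservation of every reaction
#'
#' Multiplies each stoichiometric column with the molecular weight
#' vector; a closed balance gives a residual of zero. Internal reactions
#' whose absolute residual exceeds `tol` are flagged unless they carry
#' the `massLoss` flag (implicit by-product sink) or are a biomass
#' drain. Exchange (non-internal) columns legitimately carry the mass
#' exchanged with the unrepresented external species; their residuals
#' are reported but not flagged.
#'
#' @param net a [MetabolicNetwork-class]
#' @param tol absolute tolerance, g/mol
#' @return list with `residuals` (named, g/mol per unit flux) and
#'   `flagged` (reaction ids violating conservation)
#' @export
auditMassConservation <- function(net, tol = 1e-6) {
  N <- net@stoichiometry
  w <- molecularWeights(net)
  used <- rowSums(N != 0) > 0
  if (any(used & is.na(w)))
    stop("missing molecular weight for compound(s): ",
         paste(names(w)[used & is.na(w)], collapse = ", "))
  w0 <- ifelse(is.na(w), 0, w)
  res <- as.numeric(crossprod(w0, N))
  names(res) <- colnames(N)
  rd <- net@reactionData
  bad <- abs(res) > tol & rd$internal & !rd$massLoss & !rd$biomass
  list(residuals = res, flagged = rd$id[bad], tol = tol)
}

#' Numerical rank and orthonormal null-space basis
#'
#' Singular-value based: singular values above `tol` times the largest
#' one count toward the rank; the remaining right singular vectors span
#' the kernel (orthonormal). Rank plus kernel dimension always equals
#' the number of columns.
#'
#' @param mat numeric matrix
#' @param tol relative singular-value threshold
#' @return list with `basis` (columns span the kernel), `rank`, `tol`
#' @export
rankAndNullspace <- function(mat, tol = 1e-9) {
  mat <- as.matrix(mat)
  if (!length(mat)) stop("empty matrix")
  sv <- svd(mat, nu = 0, nv = ncol(mat))
  d <- sv$d
  r <- if (length(d)) sum(d > tol * max(d, 0) & d > 0) else 0L
  basis <- sv$v[, seq_len(ncol(mat) - r) + r, drop = FALSE]
  rownames(basis) <- colnames(mat)
  list(basis = basis, rank = as.integer(r), tol = tol)
}

#' Cycle basis of the internal sub-network
#'
#' The null space of the internal-columns submatrix N' spans the
#' thermodynamic cycles of the network; its basis vectors are indexed
#' by the internal reaction ids.
#'
#' @param net a [MetabolicNetwork-class]
#' @param tol relative rank tolerance
#' @return as [rankAndNullspace()], rows named by internal reactions
#' @export
internalCycleBasis <- function(net, tol = 1e-9) {
  keep <- net@reactionData$internal
  if (!any(keep)) stop("network has no internal reactions")
  Np <- net@stoichiometry[, keep, drop = FALSE]
  rankAndNullspace(Np, tol)
}

#' Specific growth rate from a flux vector
#'
#' Evaluates mu = w' N r with the mmol-to-g conversion (factor 1000)
#' applied, in 1/h. Mass-conserving internal columns contribute
#' nothing; uptake columns contribute positively, excretion and
#' by-product losses negatively. Biomass drain columns (mass converted
#' into biomass rather than lost) contribute positively.
#'
#' @param net a [MetabolicNetwork-class] with molecular weights
#' @param r flux vector, mmol/gDW/h, length = number of reactions
#' @return specific growth rate, 1/h (may be negative for net mass loss)
#' @export
growthRateFromFluxes <- function(net, r) {
  N <- net@stoichiometry
  if (length(r) != ncol(N))
    stop(sprintf("flux vector length %d does not match %d reactions",
                 length(r), ncol(N)))
  w <- molecularWeights(net)
  if (anyNA(w)) stop("missing molecular weight for compound(s): ",
                     paste(names(w)[is.na(w)], collapse = ", "))
  contrib <- as.numeric(crossprod(w, N)) * as.numeric(r) / .MMOL_PER_MOL
  sgn <- ifelse(net@reactionData$biomass, -1, 1)
  sum(sgn * contrib)
}

#' Dilution-to-uptake ratio
#'
#' Compares an uptake rate against the dilution term mu * c of the
#' concentration balance; a large ratio justifies dropping the dilution
#' term in steady-state flux analysis.
#'
#' @param uptake uptake rate, mmol/gDW/h
#' @param mu specific growth rate, 1/h
#' @param conc intracellular concentration, mmol/gDW
#' @return the dimensionless ratio uptake / (mu * conc)
#' @export
dilutionRatio <- function(uptake, mu, conc) {
  if (any(c(uptake, mu, conc) <= 0))
    stop("uptake, mu and conc must all be positive (ratio undefined otherwise)")
  uptake / (mu * conc)
}
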