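#' @include AllClasses.R network_core.R
NULL

## Null-space tableau enumeration of elementary flux modes
## (Schuster-style). Reversible reactions are split into forward and
## backward columns, the classic irreversible tableau algorithm is run
## (pairwise positive combinations cancelling one metabolite at a time,
## with support-minimality filtering), and the split is folded back.

.efmNormalize <- function(v, uptakeIdx) {
  sup <- which(abs(v) > 1e-10)
  up <- intersect(uptakeIdx, sup)
  if (length(up)) {
    v / v[up[1]]
  } else {
    v / v[sup[1]]
  }
}

#' Enumerate elementary flux modes
#'
#' Exhaustively enumerates the support-minimal steady-state flux
#' distributions of a small network (guard: at most 20 reactions).
#' Every returned mode satisfies `N r = 0` on all balanced compounds,
#' respects irreversibilities, has support-minimality verified (the
#' stoichiometric submatrix restricted to the support has nullity one),
#' and is normalized to unit uptake flux when an uptake reaction is in
#' the support, else to +1 in its first nonzero coordinate.
#'
#' @param net a [MetabolicNetwork-class]
#' @param reversible logical per reaction; default: `lb < 0`.
#' @return list with `modes` (q x m matrix, one column per mode),
#'   `supports` (list of integer index vectors), and `mu` per mode when
#'   all molecular weights are known.
#' @export
enumerateEFMs <- function(net, reversible = NULL) {
  N <- net@stoichiometry[!net@compoundData$external, , drop = FALSE]
  q <- ncol(N)
  if (q > 20)
    stop("network too large for exhaustive EFM enumeration (q > 20); ",
         "use a dedicated EFM tool for genome-scale models")
  rd <- net@reactionData
  if (is.null(reversible)) reversible <- rd$lb < 0
  ## split reversible columns
  Ns <- cbind(N, -N[, reversible, drop = FALSE])
  origIdx <- c(seq_len(q), which(reversible))
  sgn <- c(rep(1, q), rep(-1, sum(reversible)))
  qs <- ncol(Ns)
  ## tableau: rows = candidate modes over split fluxes | metabolite residuals
  Tm <- cbind(diag(qs), t(Ns))
  modeCols <- seq_len(qs)
  dropNonMinimal <- function(M) {
    if (nrow(M) <= 1) return(M)
    sup <- lapply(seq_len(nrow(M)), function(i)
      which(abs(M[i, modeCols]) > 1e-10))
    keep <- rep(TRUE, nrow(M))
    for (i in seq_len(nrow(M))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(M))) {
        if (i == j || !keep[j]) next
        if (length(sup[[j]]) < length(sup[[i]]) &&
            all(sup[[j]] %in% sup[[i]])) { keep[i] <- FALSE; break }
      }
    }
    M[keep, , drop = FALSE]
  }
  for (j in seq_len(nrow(Ns))) {
    col <- Tm[, qs + j]
    zero <- abs(col) <= 1e-10
    keepRows <- Tm[zero, , drop = FALSE]
    pos <- which(col > 1e-10); neg <- which(col < -1e-10)
    if (length(pos) && length(neg)) {
      combos <- matrix(0, length(pos) * length(neg), ncol(Tm))
      k <- 0L
      for (i in pos) for (m in neg) {
        k <- k + 1L
        combos[k, ] <- col[i] * Tm[m, ] - col[m] * Tm[i, ]
      }
      combos[abs(combos) < 1e-12] <- 0
      ## rescale to max 1 for numerical stability
      combos <- t(apply(combos, 1, function(v) v / max(abs(v))))
      keepRows <- rbind(keepRows, combos)
    }
    Tm <- dropNonMinimal(keepRows)
    if (!nrow(Tm)) break
  }
  ## fold split fluxes back and discard futile forward/backward pairs
  modes <- list(); sups <- list()
  uptakeIdx <- which(!rd$internal &
                       apply(N, 2, function(cl) all(cl >= 0) && any(cl > 0)))
  if (nrow(Tm)) for (i in seq_len(nrow(Tm))) {
    vsplit <- Tm[i, modeCols]
    v <- numeric(q)
    for (k in seq_len(qs)) v[origIdx[k]] <- v[origIdx[k]] + sgn[k] * vsplit[k]
    v[abs(v) < 1e-10] <- 0
    if (all(v == 0)) next                      # futile split pair
    sup <- which(v != 0)
    ## verify support minimality: nullity of N restricted to support is 1
    ns <- rankAndNullspace(N[, sup, drop = FALSE])
    if (ncol(ns$basis) != 1) next
    if (any(abs(N %*% v) > 1e-8 * max(1, max(abs(v))))) next
    if (any(!reversible[sup] & v[sup] < 0)) next
    v <- .efmNormalize(v, uptakeIdx)
    key <- paste(sup, collapse = ",")
    if (!is.null(modes[[key]])) next
    modes[[key]] <- v; sups[[key]] <- sup
  }
  M <- if (length(modes)) do.call(cbind, modes) else
    matrix(0, q, 0)
  rownames(M) <- rd$id
  colnames(M) <- if (length(modes)) sprintf("efm%d", seq_along(modes)) else
    character()
  w <- molecularWeights(net)
  mu <- if (!anyNA(w) && ncol(M))
    apply(M, 2, function(v) growthRateFromFluxes(net, v)) else NULL
  list(modes = M, supports = unname(sups), mu = mu)
}
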