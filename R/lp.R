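#' @include AllClasses.R
NULL

## Internal dense LP machinery.
##
## solveLP() solves   min/max c'x   s.t.  Aeq x = beq, Aub x <= bub,
## lb <= x <= ub   via a two-phase primal simplex on the standard form
## min c'y, A y = b, y >= 0 (variables shifted by their finite lower
## bounds, slacks appended for inequality rows). Bland's anti-cycling
## rule guarantees termination; problem sizes in this package are tiny
## (tens of variables), so the dense tableau is appropriate.
.LP_BIG <- 1e7
.LP_TOL <- 1e-9

## min c'x, A x = b, x >= 0. Returns list(x, value, status).
## Rows and columns are equilibrated first so that badly scaled inputs
## (e.g. turnover numbers ~1e6 against enzyme levels ~1e-7) pivot
## reliably.
.simplexStandard <- function(cc, A, b) {
  m <- nrow(A); n <- ncol(A)
  rs <- apply(abs(A), 1, max)
  rs[rs == 0] <- 1
  A <- A / rs; b <- b / rs
  cs <- apply(abs(A), 2, max)
  cs[cs == 0] <- 1
  A <- sweep(A, 2, cs, "/")
  cc0 <- cc
  cc <- cc / cs
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  ## full column set = structural variables + phase-1 artificials
  Afull <- cbind(A, diag(m))
  nf <- n + m
  refactor <- function(basis) {
    ## rebuild the tableau from the original matrix to remove pivot drift
    B <- Afull[, basis, drop = FALSE]
    Tm <- tryCatch(solve(B, cbind(Afull, b)), error = function(e) NULL)
    if (is.null(Tm)) Tm <- qr.solve(B, cbind(Afull, b))
    Tm
  }
  runSimplex <- function(Tm, basis, obj, active) {
    ## Dantzig pricing with a Bland fallback (anti-cycling); among ratio
    ## ties the largest pivot element leaves, for numerical stability.
    it <- 0L
    maxDantzig <- 200L * (m + n)
    repeat {
      it <- it + 1L
      if (it > 4L * maxDantzig)
        stop("simplex iteration limit reached; the LP is numerically ",
             "degenerate")
      cb <- obj[basis]
      red <- obj[active] -
        as.numeric(crossprod(Tm[, active, drop = FALSE], cb))
      enter <- which(red < -.LP_TOL)
      if (!length(enter))
        return(list(Tm = Tm, basis = basis, optimal = TRUE))
      j <- if (it <= maxDantzig) active[enter[which.min(red[enter])]]
           else min(active[enter])
      col <- Tm[, j]
      pos <- which(col > .LP_TOL)
      if (!length(pos))
        return(list(Tm = Tm, basis = basis, optimal = FALSE))
      ratio <- Tm[pos, ncol(Tm)] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + .LP_TOL * (1 + abs(rmin))]
      i <- if (it <= maxDantzig) cand[which.max(col[cand])]
           else cand[which.min(basis[cand])]
      piv <- Tm[i, j]
      Tm[i, ] <- Tm[i, ] / piv
      for (k in seq_len(nrow(Tm))) if (k != i && abs(Tm[k, j]) > 0)
        Tm[k, ] <- Tm[k, ] - Tm[k, j] * Tm[i, ]
      basis[i] <- j
      if (it %% 40L == 0L) Tm <- refactor(basis)
    }
  }
  basis <- n + seq_len(m)
  Tm <- cbind(Afull, b)
  obj1 <- c(rep(0, n), rep(1, m))
  r1 <- runSimplex(Tm, basis, obj1, seq_len(nf))
  basis <- r1$basis
  Tm <- refactor(basis)
  phase1 <- sum(obj1[basis] * Tm[, ncol(Tm)])
  if (phase1 > 1e-7) return(list(status = "infeasible"))
  ## drive remaining artificials out of the basis where possible
  for (i in seq_len(m)) {
    if (basis[i] <= n) next
    j <- setdiff(which(abs(Tm[i, seq_len(n)]) > 1e-7), basis)
    if (!length(j)) next                 # redundant row: artificial stays at 0
    j <- j[which.max(abs(Tm[i, j]))]
    Tm[i, ] <- Tm[i, ] / Tm[i, j]
    for (k in seq_len(m)) if (k != i && abs(Tm[k, j]) > 0)
      Tm[k, ] <- Tm[k, ] - Tm[k, j] * Tm[i, ]
    basis[i] <- j
  }
  Tm <- refactor(basis)
  obj2 <- c(cc, rep(0, m))               # artificials pinned by cost 0 at 0
  r2 <- runSimplex(Tm, basis, obj2, seq_len(n))
  if (!r2$optimal) return(list(status = "unbounded"))
  basis <- r2$basis
  Tm <- refactor(basis)
  y <- numeric(nf)
  y[basis] <- Tm[, ncol(Tm)]
  if (sum(y[n + seq_len(m)]) > 1e-7) return(list(status = "infeasible"))
  x <- y[seq_len(n)] / cs                # undo column equilibration
  list(status = "optimal", x = x, value = sum(cc0 * x))
}

solveLP <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                    lb = NULL, ub = NULL, maximize = FALSE) {
  n <- length(obj)
  if (is.null(lb)) lb <- rep(-Inf, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  lb <- rep_len(pmax(lb, -.LP_BIG), n)
  ub <- rep_len(pmin(ub, .LP_BIG), n)
  if (any(lb > ub))
    return(list(x = rep(NA_real_, n), value = NA_real_,
                status = "infeasible"))
  cc <- if (maximize) -obj else obj
  ## shift y = x - lb; upper bounds and Aub rows become slack rows
  nUb <- length(bub)
  ## finite upper-bound rows (skip the artificial big box where possible)
  ubRows <- which(is.finite(ub) & ub < .LP_BIG)
  ## every variable needs SOME upper cap to keep the cone bounded only
  ## if the objective is unbounded; rely on the big box for those
  ubRows <- seq_len(n)
  A1 <- NULL; b1 <- NULL
  if (nUb) {
    A1 <- Aub
    b1 <- bub - as.numeric(Aub %*% lb)
  }
  A1 <- rbind(A1, diag(n)[ubRows, , drop = FALSE])
  b1 <- c(b1, (ub - lb)[ubRows])
  mUb <- nrow(A1)
  A2 <- NULL; b2 <- NULL
  if (!is.null(Aeq)) {
    A2 <- Aeq
    b2 <- beq - as.numeric(Aeq %*% lb)
  }
  ## standard form with slacks s >= 0 on the inequality rows
  A <- rbind(cbind(A1, diag(mUb)),
             if (!is.null(A2)) cbind(A2, matrix(0, nrow(A2), mUb)))
  b <- c(b1, b2)
  res <- .simplexStandard(c(cc, numeric(mUb)), A, b)
  if (res$status != "optimal")
    return(list(x = rep(NA_real_, n), value = NA_real_, status = res$status))
  x <- res$x[seq_len(n)] + lb
  status <- "optimal"
  ## pressing against the artificial box on an originally infinite bound
  atBox <- (abs(x - .LP_BIG) < 1e-3 & !is.finite(ub)) |
           (abs(x + .LP_BIG) < 1e-3 & !is.finite(lb))
  if (any(atBox)) status <- "unbounded"
  list(x = x, value = sum(obj * x), status = status)
}

## Flux-space LP used by all FBA variants.
##
## extra: list(n, obj, lb, ub, Aeq, beq, Aub, bub) appends variables
## after the q flux variables; extra constraint rows may reference them.
fluxLP <- function(net, objCoef, maximize, fixed = list(),
                   extra = NULL) {
  rd <- net@reactionData
  q <- nrow(rd)
  N <- net@stoichiometry
  lb <- rd$lb; ub <- rd$ub
  for (id in names(fixed)) {
    j <- match(id, rd$id)
    if (is.na(j)) stop("unknown reaction in 'fixed': ", id)
    v <- fixed[[id]]
    if (v < rd$lb[j] - 1e-9 || v > rd$ub[j] + 1e-9)
      stop(sprintf("fixed value %g for %s outside bounds [%g, %g]",
                   v, id, rd$lb[j], rd$ub[j]))
    lb[j] <- v; ub[j] <- v
  }
  N <- N[!net@compoundData$external, , drop = FALSE]
  nx <- if (is.null(extra)) 0L else extra$n
  obj <- c(objCoef, if (nx) extra$obj else NULL)
  Aeq <- cbind(N, matrix(0, nrow(N), nx))
  beq <- rep(0, nrow(N))
  if (!is.null(extra$Aeq)) { Aeq <- rbind(Aeq, extra$Aeq); beq <- c(beq, extra$beq) }
  Aub <- extra$Aub; bub <- extra$bub
  lbAll <- c(lb, if (nx) extra$lb else NULL)
  ubAll <- c(ub, if (nx) extra$ub else NULL)
  res <- solveLP(obj, Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
                 lb = lbAll, ub = ubAll, maximize = maximize)
  res$q <- q
  res
}
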