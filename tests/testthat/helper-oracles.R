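# Independent brute-force oracles used across the suite.

# Elementary flux modes by exhaustive support enumeration: a support is
# elementary iff the balanced stoichiometric submatrix has nullity one,
# the kernel vector is nonzero on the whole support and sign-feasible,
# and no admissible proper subset exists.
bruteForceEFMs <- function(net, reversible = NULL) {
  N <- stoichiometry(net)[!compounds(net)$external, , drop = FALSE]
  q <- ncol(N)
  rd <- reactions(net)
  if (is.null(reversible)) reversible <- rd$lb < 0
  valid <- list()
  for (code in seq_len(2^q - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(q) - 1)) > 0)
    ns <- rankAndNullspace(N[, S, drop = FALSE])
    if (ncol(ns$basis) != 1) next
    v <- ns$basis[, 1]
    if (any(abs(v) < 1e-9)) next              # kernel not fully supported
    full <- numeric(q); full[S] <- v
    ok <- function(u) all(u[S][!reversible[S]] >= -1e-12)
    if (ok(full)) valid[[length(valid) + 1]] <- full
    else if (ok(-full)) valid[[length(valid) + 1]] <- -full
  }
  sup <- lapply(valid, function(v) which(abs(v) > 1e-9))
  keep <- vapply(seq_along(sup), function(i)
    !any(vapply(seq_along(sup), function(j)
      j != i && length(sup[[j]]) < length(sup[[i]]) &&
        all(sup[[j]] %in% sup[[i]]), TRUE)), TRUE)
  list(modes = valid[keep], supports = sup[keep])
}

supportKey <- function(idx) paste(sort(idx), collapse = ",")

# random feasible steady-state flux vectors obtained by optimizing
# random linear objectives (used for dominance / optimality checks)
randomFeasibleFluxes <- function(net, n, fixed = list(), seed = 1) {
  set.seed(seed)
  out <- list()
  ids <- reactions(net)$id
  for (i in seq_len(n)) {
    co <- setNames(rnorm(length(ids)), ids)
    sol <- solveFBA(net, fluxObjective("linear", co,
                                       sense = sample(c("max", "min"), 1)),
                    fixed = fixed, tieBreak = FALSE)
    if (solutionStatus(sol) == "optimal")
      out[[length(out) + 1]] <- fluxes(sol)
  }
  out
}

toyKeq <- c(r1 = 10, r2 = 2, r3 = 3, r4 = 18)  # loop-consistent: 2 * 3^2 = 18

toyThermoSpec <- function(net = toyNetwork()) {
  thermoSpec(keqToDg0(toyKeq), net = net)
}
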