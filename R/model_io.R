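#' @include AllClasses.R AllGenerics.R
NULL

.defaultReactionDefaults <- function() {
  list(lb = -1000, ub = 1000, internal = TRUE, dg0 = NA_real_,
       kcat = NA_real_, massLoss = FALSE, biomass = FALSE)
}

#' Construct a metabolic network
#'
#' Builds a [MetabolicNetwork-class] from a dense stoichiometric matrix
#' (rows = compounds, columns = reactions, substrates negative) and
#' optional per-compound / per-reaction annotation. Default flux bounds
#' are -1000..1000 mmol/gDW/h for reversible reactions and 0..1000 for
#' irreversible ones (set via `lb`/`ub`).
#'
#' @param stoich numeric matrix with dimnames; rows compounds, columns
#'   reactions.
#' @param mw named molecular weights, g/mol (optional).
#' @param external logical per compound (default all `FALSE`).
#' @param lb,ub flux bounds per reaction, mmol/gDW/h.
#' @param internal logical per reaction; internal reactions take part in
#'   thermodynamic cycle analysis.
#' @param dg0 standard Gibbs energies per reaction, kJ/mol.
#' @param kcat turnover numbers per reaction, 1/h.
#' @param massLoss logical per reaction: `TRUE` marks reactions with an
#'   implicit by-product sink that are deliberately not mass balanced.
#' @param biomass logical per reaction: `TRUE` marks a biomass drain.
#' @param concMin,concMax concentration bounds per compound, mmol/gDW.
#' @param massFraction biomass composition per compound, g/g (sums to 1
#'   over the non-`NA` entries).
#' @param kinetics named list of [KineticLaw-class] objects.
#' @return a validated [MetabolicNetwork-class]
#' @export
metabolicNetwork <- function(stoich, mw = NULL, external = NULL,
                             lb = NULL, ub = NULL, internal = NULL,
                             dg0 = NULL, kcat = NULL, massLoss = NULL,
                             biomass = NULL, concMin = NULL, concMax = NULL,
                             massFraction = NULL, kinetics = list()) {
  stoich <- as.matrix(stoich)
  if (is.null(rownames(stoich)) || is.null(colnames(stoich)))
    stop("stoichiometric matrix needs compound rownames and reaction colnames")
  l <- nrow(stoich); q <- ncol(stoich)
  fill <- function(x, default, n, nms) {
    if (is.null(x)) return(rep(default, n))
    if (!is.null(names(x))) {
      out <- rep(default, n); names(out) <- nms
      out[names(x)] <- x
      return(unname(out))
    }
    rep_len(x, n)
  }
  cids <- rownames(stoich); rids <- colnames(stoich)
  d <- .defaultReactionDefaults()
  cd <- data.frame(
    id = cids,
    mw = fill(mw, NA_real_, l, cids),
    external = fill(external, FALSE, l, cids),
    concMin = fill(concMin, NA_real_, l, cids),
    concMax = fill(concMax, NA_real_, l, cids),
    massFraction = fill(massFraction, NA_real_, l, cids),
    stringsAsFactors = FALSE)
  rd <- data.frame(
    id = rids,
    lb = fill(lb, d$lb, q, rids),
    ub = fill(ub, d$ub, q, rids),
    internal = fill(internal, d$internal, q, rids),
    dg0 = fill(dg0, d$dg0, q, rids),
    kcat = fill(kcat, d$kcat, q, rids),
    massLoss = fill(massLoss, d$massLoss, q, rids),
    biomass = fill(biomass, d$biomass, q, rids),
    stringsAsFactors = FALSE)
  new("MetabolicNetwork", stoichiometry = stoich, compoundData = cd,
      reactionData = rd, kinetics = kinetics)
}

#' Construct a kinetic rate law
#'
#' @param kcat forward turnover number, 1/h.
#' @param Ks,Kp named substrate/product binding constants, mmol/gDW.
#' @param orderS,orderP named molecularities (positive integers); default
#'   1 for every named binding constant.
#' @param Keq equilibrium constant; if omitted and `kcatMinus` is given it
#'   is derived from the Haldane relationship.
#' @param kcatMinus backward turnover number, 1/h (optional).
#' @param Km Michaelis constant for the irreversible MM variant.
#' @return a [KineticLaw-class]
#' @export
kineticLaw <- function(kcat, Ks = numeric(), Kp = numeric(),
                       orderS = NULL, orderP = NULL, Keq = NA_real_,
                       kcatMinus = NA_real_, Km = NA_real_) {
  if (is.null(orderS)) orderS <- setNames(rep(1, length(Ks)), names(Ks))
  if (is.null(orderP)) orderP <- setNames(rep(1, length(Kp)), names(Kp))
  if (is.na(Keq) && !is.na(kcatMinus) && length(Ks) == 1 && length(Kp) == 1)
    Keq <- kcat * Kp / (kcatMinus * Ks)
  new("KineticLaw", kcat = kcat, kcatMinus = kcatMinus,
      Ks = Ks, Kp = Kp, orderS = orderS, orderP = orderP,
      Keq = as.numeric(Keq), Km = Km)
}

.knownCompoundFields <- c("id", "mw", "external", "conc_min", "conc_max",
                          "mass_fraction")
.knownReactionFields <- c("id", "stoich", "lb", "ub", "internal", "dg0",
                          "kcat", "mass_loss", "biomass", "kinetics")

#' Load a model from its JSON description
#'
#' Reads the package's JSON model dialect:
#' `{"compounds": [{"id","mw","external","conc_min","conc_max"}, ...],`
#' `"reactions": [{"id","stoich": {id: coef}, "lb","ub","internal","dg0",`
#' `"kcat","mass_loss"}, ...], "biomass": {"fractions": {id: f}}}`.
#' Kinetic parameters nest under each reaction as
#' `{"kcat","Ks":{id:val},"Kp":{id:val},"orders":{id:n},"Keq"}`.
#' Unknown fields are ignored with a warning; a reaction referencing a
#' compound absent from the compound list is a validation error.
#'
#' @param path path to a JSON model file.
#' @return a [MetabolicNetwork-class]
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed model JSON in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(doc$compounds) || is.null(doc$reactions))
    stop("model JSON must have 'compounds' and 'reactions' keys")
  unknown <- unique(c(
    unlist(lapply(doc$compounds, function(x)
      setdiff(names(x), .knownCompoundFields))),
    unlist(lapply(doc$reactions, function(x)
      setdiff(names(x), .knownReactionFields)))))
  if (length(unknown))
    warning("ignoring unknown model fields: ", paste(unknown, collapse = ", "))
  cids <- vapply(doc$compounds, `[[`, "", "id")
  rids <- vapply(doc$reactions, `[[`, "", "id")
  N <- matrix(0, length(cids), length(rids), dimnames = list(cids, rids))
  for (k in seq_along(doc$reactions)) {
    st <- doc$reactions[[k]]$stoich
    if (is.null(st) || !length(st))
      stop("reaction '", rids[k], "' has empty stoichiometry")
    bad <- setdiff(names(st), cids)
    if (length(bad))
      stop("reaction '", rids[k], "' references unknown compound(s): ",
           paste(bad, collapse = ", "))
    N[names(st), k] <- unlist(st)
  }
  getf <- function(lst, field, default) {
    vapply(lst, function(x) {
      v <- x[[field]]
      if (is.null(v)) default else as.vector(v, mode = typeof(default))
    }, default)
  }
  frac <- rep(NA_real_, length(cids))
  if (!is.null(doc$biomass$fractions)) {
    fr <- unlist(doc$biomass$fractions)
    frac[match(names(fr), cids)] <- fr
  }
  kin <- list()
  for (k in seq_along(doc$reactions)) {
    kk <- doc$reactions[[k]]$kinetics
    if (!is.null(kk)) {
      kin[[rids[k]]] <- kineticLaw(
        kcat = kk$kcat,
        Ks = unlist(kk$Ks), Kp = unlist(kk$Kp),
        orderS = if (!is.null(kk$orders)) unlist(kk$orders)[names(unlist(kk$Ks))],
        orderP = if (!is.null(kk$orders)) unlist(kk$orders)[names(unlist(kk$Kp))],
        Keq = if (is.null(kk$Keq)) NA_real_ else kk$Keq)
    }
  }
  d <- .defaultReactionDefaults()
  metabolicNetwork(
    N,
    mw = setNames(getf(doc$compounds, "mw", NA_real_), cids),
    external = setNames(getf(doc$compounds, "external", FALSE), cids),
    concMin = setNames(getf(doc$compounds, "conc_min", NA_real_), cids),
    concMax = setNames(getf(doc$compounds, "conc_max", NA_real_), cids),
    massFraction = setNames(frac, cids),
    lb = setNames(getf(doc$reactions, "lb", d$lb), rids),
    ub = setNames(getf(doc$reactions, "ub", d$ub), rids),
    internal = setNames(getf(doc$reactions, "internal", d$internal), rids),
    dg0 = setNames(getf(doc$reactions, "dg0", NA_real_), rids),
    kcat = setNames(getf(doc$reactions, "kcat", NA_real_), rids),
    massLoss = setNames(getf(doc$reactions, "mass_loss", FALSE), rids),
    biomass = setNames(getf(doc$reactions, "biomass", FALSE), rids),
    kinetics = kin)
}

#' Save a model to JSON
#'
#' Inverse of [loadModel()]; `loadModel(saveModel(net, f))` reproduces
#' the stoichiometric matrix entry-wise.
#'
#' @param net a [MetabolicNetwork-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
saveModel <- function(net, path) {
  cd <- net@compoundData; rd <- net@reactionData
  N <- net@stoichiometry
  drop_na <- function(x) x[!vapply(x, function(v)
    is.null(v) || (length(v) == 1 && is.na(v)), TRUE)]
  comps <- lapply(seq_len(nrow(cd)), function(j) drop_na(list(
    id = cd$id[j], mw = cd$mw[j], external = cd$external[j],
    conc_min = cd$concMin[j], conc_max = cd$concMax[j])))
  rxns <- lapply(seq_len(nrow(rd)), function(k) {
    st <- N[, k]; st <- st[st != 0]
    out <- list(id = rd$id[k], stoich = as.list(st), lb = rd$lb[k],
                ub = rd$ub[k], internal = rd$internal[k],
                dg0 = rd$dg0[k], kcat = rd$kcat[k],
                mass_loss = rd$massLoss[k], biomass = rd$biomass[k])
    kin <- net@kinetics[[rd$id[k]]]
    if (!is.null(kin)) {
      out$kinetics <- drop_na(list(
        kcat = kin@kcat, Ks = as.list(kin@Ks), Kp = as.list(kin@Kp),
        orders = as.list(c(kin@orderS, kin@orderP)),
        Keq = kin@Keq))
    }
    drop_na(out)
  })
  doc <- list(compounds = comps, reactions = rxns)
  fr <- cd$massFraction
  if (any(!is.na(fr)))
    doc$biomass <- list(fractions = as.list(setNames(fr[!is.na(fr)],
                                                     cd$id[!is.na(fr)])))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a stoichiometric matrix from TSV
#'
#' TSV import is provided for matrices only: a rectangular table with
#' compound ids in the first column and reaction ids as header.
#'
#' @param path path to a TSV file
#' @return numeric matrix with dimnames
#' @export
readStoichiometryTSV <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' Save and reload flux solutions
#'
#' `saveSolution()` writes a TSV flux table (reaction id, flux, and,
#' when present, Gibbs energy and enzyme level columns) at full
#' precision, plus a JSON sidecar `<path>.json` holding objective value,
#' status and growth rate. An infeasible solution writes no flux rows
#' but still records its status. `readSolution()` restores the object.
#'
#' @param sol a [FluxSolution-class]
#' @param path output TSV path (sidecar becomes `<path>.json`)
#' @return `path`, invisibly
#' @export
saveSolution <- function(sol, path) {
  meta <- list(objective = sol@objectiveValue, status = sol@status,
               mu = sol@mu)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = I(17),
                              na = "null"),
             paste0(path, ".json"))
  if (sol@status != "optimal" || !length(sol@fluxes)) {
    tab <- data.frame(reaction = character(), flux = character())
  } else {
    if (any(!is.finite(sol@fluxes))) stop("solution fluxes must be finite")
    tab <- data.frame(reaction = names(sol@fluxes),
                      flux = sprintf("%.17g", sol@fluxes))
    if (length(sol@deltaG))
      tab$dG <- sprintf("%.17g", sol@deltaG[tab$reaction])
    if (length(sol@enzymes))
      tab$enzyme <- sprintf("%.17g", sol@enzymes[tab$reaction])
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname saveSolution
#' @export
readSolution <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  tab <- read.delim(path, colClasses = "character")
  sol <- new("FluxSolution",
             status = meta$status,
             objectiveValue = if (is.null(meta$objective)) NA_real_
                              else as.numeric(meta$objective),
             mu = if (is.null(meta$mu)) NA_real_ else as.numeric(meta$mu))
  if (nrow(tab)) {
    sol@fluxes <- setNames(as.numeric(tab$flux), tab$reaction)
    if ("dG" %in% names(tab))
      sol@deltaG <- setNames(as.numeric(tab$dG), tab$reaction)
    if ("enzyme" %in% names(tab))
      sol@enzymes <- setNames(as.numeric(tab$enzyme), tab$reaction)
  }
  sol
}
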