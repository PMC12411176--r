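#' @include AllClasses.R
NULL

#' Accessors for network and solution objects
#'
#' `stoichiometry()` returns the dense compounds-by-reactions matrix N,
#' `compounds()`/`reactions()` the annotation data frames,
#' `molecularWeights()` the named weight vector (g/mol),
#' `internalStoichiometry()` the submatrix N' of internal reactions.
#' On [FluxSolution-class] objects, `fluxes()`, `objectiveValue()`,
#' `solutionStatus()`, `growthRate()`, `enzymeLevels()`, `deltaG()` and
#' `logConcentrations()` extract the respective slots.
#'
#' @param object a [MetabolicNetwork-class] or [FluxSolution-class]
#' @return the requested component
#' @name accessors
#' @aliases stoichiometry compounds reactions molecularWeights
#'   internalStoichiometry fluxes objectiveValue solutionStatus
#'   growthRate enzymeLevels deltaG logConcentrations
NULL

#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @rdname accessors
#' @export
setGeneric("compounds", function(object) standardGeneric("compounds"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("molecularWeights",
           function(object) standardGeneric("molecularWeights"))
#' @rdname accessors
#' @export
setGeneric("internalStoichiometry",
           function(object) standardGeneric("internalStoichiometry"))
#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @rdname accessors
#' @export
setGeneric("solutionStatus", function(object) standardGeneric("solutionStatus"))
#' @rdname accessors
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))
#' @rdname accessors
#' @export
setGeneric("enzymeLevels", function(object) standardGeneric("enzymeLevels"))
#' @rdname accessors
#' @export
setGeneric("deltaG", function(object) standardGeneric("deltaG"))
#' @rdname accessors
#' @export
setGeneric("logConcentrations",
           function(object) standardGeneric("logConcentrations"))

#' @rdname accessors
setMethod("stoichiometry", "MetabolicNetwork",
          function(object) object@stoichiometry)
#' @rdname accessors
setMethod("compounds", "MetabolicNetwork",
          function(object) object@compoundData)
#' @rdname accessors
setMethod("reactions", "MetabolicNetwork",
          function(object) object@reactionData)
#' @rdname accessors
setMethod("molecularWeights", "MetabolicNetwork", function(object)
  setNames(object@compoundData$mw, object@compoundData$id))
#' @rdname accessors
setMethod("internalStoichiometry", "MetabolicNetwork", function(object)
  object@stoichiometry[, object@reactionData$internal, drop = FALSE])

#' @rdname accessors
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)
#' @rdname accessors
setMethod("objectiveValue", "FluxSolution",
          function(object) object@objectiveValue)
#' @rdname accessors
setMethod("solutionStatus", "FluxSolution", function(object) object@status)
#' @rdname accessors
setMethod("growthRate", "FluxSolution", function(object) object@mu)
#' @rdname accessors
setMethod("enzymeLevels", "FluxSolution", function(object) object@enzymes)
#' @rdname accessors
setMethod("deltaG", "FluxSolution", function(object) object@deltaG)
#' @rdname accessors
setMethod("logConcentrations", "FluxSolution",
          function(object) object@logConc)
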