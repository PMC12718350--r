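## Accessor generics.  Slot access stays internal to the package; user code
## goes through these.

#' @rdname Snapshot-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname Snapshot-class
#' @export
setGeneric("stateMatrix", function(object) standardGeneric("stateMatrix"))

#' @rdname Snapshot-class
#' @export
setGeneric("cellMeta", function(object) standardGeneric("cellMeta"))

#' @rdname Snapshot-class
#' @export
setGeneric("isEmbedding", function(object) standardGeneric("isEmbedding"))

#' @describeIn Snapshot-class number of cells.
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

setMethod("cellIds", "Snapshot", function(object) object@cellIds)
setMethod("stateMatrix", "Snapshot", function(object) object@values)
setMethod("cellMeta", "Snapshot", function(object) object@meta)
setMethod("isEmbedding", "Snapshot", function(object) object@isEmbedding)
setMethod("nCells", "Snapshot", function(object) nrow(object@values))

#' @rdname StatePartition-class
#' @export
setGeneric("initialStates", function(object) standardGeneric("initialStates"))

#' @rdname StatePartition-class
#' @export
setGeneric("intermediateStates",
           function(object) standardGeneric("intermediateStates"))

#' @rdname StatePartition-class
#' @export
setGeneric("terminalStates", function(object) standardGeneric("terminalStates"))

#' @rdname StatePartition-class
#' @export
setGeneric("fateOf", function(object) standardGeneric("fateOf"))

#' @rdname StatePartition-class
#' @export
setGeneric("fateClasses", function(object) standardGeneric("fateClasses"))

#' @rdname StatePartition-class
#' @export
setGeneric("auxEnabled", function(object) standardGeneric("auxEnabled"))

#' @describeIn StatePartition-class number of initial states `n0`.
#' @export
setGeneric("nInitial", function(object) standardGeneric("nInitial"))

#' @describeIn StatePartition-class number of intermediate states `n`.
#' @export
setGeneric("nIntermediate", function(object) standardGeneric("nIntermediate"))

#' @describeIn StatePartition-class number of terminal states `nF`.
#' @export
setGeneric("nTerminal", function(object) standardGeneric("nTerminal"))

setMethod("cellIds", "StatePartition", function(object) object@cellIds)
setMethod("initialStates", "StatePartition", function(object) object@X0)
setMethod("intermediateStates", "StatePartition", function(object) object@X)
setMethod("terminalStates", "StatePartition", function(object) object@XF)
setMethod("fateOf", "StatePartition", function(object) object@fateOf)
setMethod("fateClasses", "StatePartition", function(object) object@fateClasses)
setMethod("auxEnabled", "StatePartition", function(object) object@auxEnabled)
setMethod("nInitial", "StatePartition", function(object) length(object@X0))
setMethod("nIntermediate", "StatePartition", function(object) length(object@X))
setMethod("nTerminal", "StatePartition", function(object) length(object@XF))

#' @rdname CostSet-class
#' @param object a `CostSet`.
#' @param what which block to extract.
#' @export
setGeneric("costMatrix",
           function(object, what = c("C0X", "C0F", "CXX", "CXF"))
               standardGeneric("costMatrix"))

setMethod("costMatrix", "CostSet", function(object, what) {
    what <- match.arg(what, c("C0X", "C0F", "CXX", "CXF"))
    slot(object, what)
})

#' @describeIn CostSet-class the median divided out by [normalizeCosts()].
#' @export
setGeneric("normalizationFactor",
           function(object) standardGeneric("normalizationFactor"))
setMethod("normalizationFactor", "CostSet",
          function(object) object@normalizationFactor)

#' @describeIn CostSet-class the auxiliary-state cost (`NA` when absent).
#' @export
setGeneric("auxCostQ", function(object) standardGeneric("auxCostQ"))
setMethod("auxCostQ", "CostSet", function(object) object@auxCostQ)

## StagePlans marginals ------------------------------------------------------

#' Latent marginals of stagewise plans
#'
#' `muTilde(plans, t)` is the mass continuing in the system at stage `t`
#' (row sums of the continuing plan), `muHat(plans, t)` the mass exiting to
#' the terminal tier at stage `t` (row sums of the exiting plan), and
#' `nuHat(plans, t)` the mass received by each terminal cell at stage `t`
#' (column sums of the exiting plan).  Stages are indexed `t = 0 .. T - 1`.
#'
#' @param plans a [StagePlans-class].
#' @param t stage index, `0 .. T - 1` (`muTilde` only up to `T - 2`).
#' @return numeric vector.
#' @export
muTilde <- function(plans, t) {
    stopifnot(t >= 0, t <= plans@nStages - 2L)
    rowSums(plans@Mtilde[[t + 1L]])
}

#' @rdname muTilde
#' @export
muHat <- function(plans, t) {
    stopifnot(t >= 0, t <= plans@nStages - 1L)
    rowSums(plans@Mhat[[t + 1L]])
}

#' @rdname muTilde
#' @export
nuHat <- function(plans, t) {
    stopifnot(t >= 0, t <= plans@nStages - 1L)
    colSums(plans@Mhat[[t + 1L]])
}

#' @describeIn StagePlans-class number of transport stages.
#' @param object a `StagePlans`.
#' @export
setGeneric("nStages", function(object) standardGeneric("nStages"))
setMethod("nStages", "StagePlans", function(object) object@nStages)
setMethod("nStages", "MsotConfig", function(object) object@nStages)

## SolveReport ---------------------------------------------------------------

#' @describeIn SolveReport-class total linear transport cost.
#' @param object a `SolveReport`.
#' @export
setGeneric("transportCost", function(object) standardGeneric("transportCost"))
setMethod("transportCost", "SolveReport", function(object) object@transportCost)

#' @describeIn SolveReport-class `TRUE` when the solve met its tolerance.
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
setMethod("converged", "SolveReport", function(object) object@converged)

#' @describeIn SolveReport-class `epsilonStart / proxStepsDone`.
#' @export
setGeneric("effectiveEpsilon",
           function(object) standardGeneric("effectiveEpsilon"))
setMethod("effectiveEpsilon", "SolveReport",
          function(object) object@effectiveEpsilon)
setMethod("effectiveEpsilon", "MsotConfig",
          function(object) object@epsilonStart / object@proxIters)

## TransitionModel -----------------------------------------------------------

#' @describeIn TransitionModel-class the row-stochastic transition matrix.
#' @param object a `TransitionModel`.
#' @export
setGeneric("transitionMatrix",
           function(object) standardGeneric("transitionMatrix"))
setMethod("transitionMatrix", "TransitionModel", function(object) object@P)

#' @describeIn TransitionModel-class the unnormalized aggregated mass matrix.
#' @export
setGeneric("aggregatedMass", function(object) standardGeneric("aggregatedMass"))
setMethod("aggregatedMass", "TransitionModel", function(object) object@A)

setMethod("cellIds", "TransitionModel", function(object) object@cellIds)

## ClonalReference -----------------------------------------------------------

#' @describeIn ClonalReference-class reference distributions of eligible cells
#'   (rows named by cell id).
#' @param object a `ClonalReference`.
#' @export
setGeneric("referenceFates", function(object) standardGeneric("referenceFates"))
setMethod("referenceFates", "ClonalReference", function(object) {
    object@ref[object@eligible, , drop = FALSE]
})

#' @describeIn ClonalReference-class logical eligibility mask, named by cell id.
#' @export
setGeneric("eligibleCells", function(object) standardGeneric("eligibleCells"))
setMethod("eligibleCells", "ClonalReference", function(object) {
    stats::setNames(object@eligible, object@cellIds)
})

setMethod("cellIds", "ClonalReference", function(object) object@cellIds)
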