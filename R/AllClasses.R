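#' @import methods
NULL

## ---------------------------------------------------------------------------
## Snapshot
## ---------------------------------------------------------------------------

#' Snapshot of single-cell states
#'
#' A `Snapshot` holds a cells-by-features matrix (raw counts, or a processed
#' expression matrix) or a cells-by-dimensions embedding, together with stable
#' cell identifiers and optional per-cell metadata.  Cells are rows
#' throughout; the `isEmbedding` flag records whether the values are
#' coordinates in a metric space (costs are computed directly on them) or
#' expression values (which are preprocessed and projected first).
#'
#' @slot values numeric matrix, cells x features (or cells x dims).
#' @slot cellIds character vector of unique cell identifiers, one per row.
#' @slot isEmbedding logical scalar; `TRUE` when `values` are coordinates.
#' @slot meta `data.frame` of per-cell metadata (zero columns allowed).
#'
#' @seealso [Snapshot()], [preprocessCounts()], [pcaEmbed()]
#' @exportClass Snapshot
setClass("Snapshot",
         slots = c(values = "matrix",
                   cellIds = "character",
                   isEmbedding = "logical",
                   meta = "data.frame"))

setValidity("Snapshot", function(object) {
    msgs <- character()
    v <- object@values
    if (!is.numeric(v))
        msgs <- c(msgs, "'values' must be a numeric matrix")
    if (length(object@cellIds) != nrow(v))
        msgs <- c(msgs, "number of cellIds must equal nrow(values)")
    if (anyDuplicated(object@cellIds))
        msgs <- c(msgs, "cellIds must be unique")
    if (length(object@isEmbedding) != 1L || is.na(object@isEmbedding))
        msgs <- c(msgs, "'isEmbedding' must be TRUE or FALSE")
    if (nrow(object@meta) > 0L && nrow(object@meta) != nrow(v))
        msgs <- c(msgs, "meta must have one row per cell (or none)")
    if (length(v) && !all(is.finite(v)))
        msgs <- c(msgs, "matrix entries must be finite")
    else if (isFALSE(object@isEmbedding) && length(v) && any(v < 0))
        msgs <- c(msgs, "count matrix entries must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Construct a Snapshot
#'
#' @param values numeric matrix, cells in rows.  A plain vector is treated as
#'   a one-column matrix.
#' @param cellIds character vector of unique identifiers; defaults to the
#'   row names of `values`, or `cell_1 ... cell_n`.
#' @param isEmbedding logical; `TRUE` when `values` are coordinates in a
#'   metric space rather than raw counts.
#' @param meta optional `data.frame` of per-cell metadata.
#'
#' @return A [Snapshot-class] object.
#' @examples
#' sn <- Snapshot(matrix(rpois(20, 5), nrow = 4), isEmbedding = FALSE)
#' nCells(sn)
#' @export
Snapshot <- function(values, cellIds = NULL, isEmbedding = FALSE,
                     meta = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(cellIds)) {
        cellIds <- if (!is.null(rownames(values))) rownames(values)
                   else paste0("cell_", seq_len(nrow(values)))
    }
    if (anyDuplicated(cellIds)) stop("cellIds must be unique")
    rownames(values) <- cellIds
    if (is.null(meta)) meta <- data.frame(row.names = cellIds)
    new("Snapshot", values = values, cellIds = as.character(cellIds),
        isEmbedding = isEmbedding, meta = meta)
}

## ---------------------------------------------------------------------------
## StatePartition
## ---------------------------------------------------------------------------

#' Partition of cells into initial, intermediate and terminal states
#'
#' Index sets `X0` (initial states, e.g. stem cells), `X` (intermediate
#' states) and `XF` (terminal states, e.g. lineage entry points), pairwise
#' disjoint and jointly covering all modelled cells.  Each terminal cell
#' carries a fate-class label; the declaration order of `fateClasses` is the
#' tie-break order used downstream.  When the auxiliary-state extension is
#' enabled the partition additionally contains one artificial member per
#' tier, and the auxiliary terminal forms the fate class `"unknown"`.
#'
#' @slot cellIds character vector of all modelled cells, in snapshot order
#'   (auxiliary states, when present, are appended at the end).
#' @slot X0,X,XF integer index vectors into `cellIds` (1-based).
#' @slot fateOf character vector parallel to `XF`: the fate class of each
#'   terminal cell.
#' @slot fateClasses character vector of fate-class labels in declaration
#'   order.
#' @slot auxEnabled logical; `TRUE` after [augmentAuxiliary()].
#'
#' @seealso [statePartition()], [augmentAuxiliary()], [readRoles()]
#' @exportClass StatePartition
setClass("StatePartition",
         slots = c(cellIds = "character",
                   X0 = "integer", X = "integer", XF = "integer",
                   fateOf = "character",
                   fateClasses = "character",
                   auxEnabled = "logical"))

setValidity("StatePartition", function(object) {
    msgs <- character()
    N <- length(object@cellIds)
    idx <- c(object@X0, object@X, object@XF)
    if (anyDuplicated(object@cellIds))
        msgs <- c(msgs, "cellIds must be unique")
    if (length(idx) && (min(idx) < 1L || max(idx) > N))
        msgs <- c(msgs, "index sets must point into cellIds")
    if (anyDuplicated(idx))
        msgs <- c(msgs, "X0, X and XF must be pairwise disjoint")
    if (length(idx) != N)
        msgs <- c(msgs, "X0, X and XF must jointly cover all cells")
    if (length(object@X0) < 1L)
        msgs <- c(msgs, "at least one initial state is required")
    if (length(object@XF) < 1L)
        msgs <- c(msgs, "at least one terminal state is required")
    if (length(object@fateOf) != length(object@XF))
        msgs <- c(msgs, "every terminal state needs a fate label")
    if (!all(object@fateOf %in% object@fateClasses))
        msgs <- c(msgs, "fateOf labels must be drawn from fateClasses")
    if (!all(object@fateClasses %in% object@fateOf))
        msgs <- c(msgs, "every fate class must have at least one terminal cell")
    if (length(msgs)) msgs else TRUE
})

#' Construct a StatePartition
#'
#' @param cellIds character vector of all modelled cells.
#' @param initial,terminal character vectors of cell ids designated as
#'   initial and terminal states; all remaining cells become intermediates.
#' @param fateOf character vector parallel to `terminal` giving each
#'   terminal cell's fate class.
#' @param fateClasses optional explicit class ordering; defaults to order of
#'   first appearance in `fateOf`.
#'
#' @return A [StatePartition-class].
#' @examples
#' p <- statePartition(paste0("c", 1:5), initial = "c1",
#'                     terminal = c("c4", "c5"), fateOf = c("A", "B"))
#' nIntermediate(p)
#' @export
statePartition <- function(cellIds, initial, terminal, fateOf,
                           fateClasses = NULL) {
    cellIds <- as.character(cellIds)
    bad <- setdiff(c(initial, terminal), cellIds)
    if (length(bad))
        stop("unknown cell ids in roles: ", paste(bad, collapse = ", "))
    if (length(intersect(initial, terminal)))
        stop("a cell cannot be both initial and terminal")
    if (length(fateOf) != length(terminal))
        stop("'fateOf' must have one label per terminal cell")
    X0 <- match(initial, cellIds)
    XF <- match(terminal, cellIds)
    X <- setdiff(seq_along(cellIds), c(X0, XF))
    if (is.null(fateClasses)) fateClasses <- unique(fateOf)
    new("StatePartition", cellIds = cellIds,
        X0 = as.integer(X0), X = as.integer(X), XF = as.integer(XF),
        fateOf = as.character(fateOf),
        fateClasses = as.character(fateClasses),
        auxEnabled = FALSE)
}

## ---------------------------------------------------------------------------
## CostSet
## ---------------------------------------------------------------------------

#' Squared-Euclidean transition costs between cell tiers
#'
#' Four cost matrices covering every modelled transition: initial to
#' intermediate (`C0X`), initial to terminal (`C0F`), intermediate to
#' intermediate (`CXX`) and intermediate to terminal (`CXF`).
#' `normalizationFactor` records the pooled median divided out by
#' [normalizeCosts()] (1 when unnormalized); `auxCostQ` records the fixed
#' auxiliary-state cost once [augmentAuxiliary()] has been applied (`NA`
#' otherwise).
#'
#' @slot C0X,C0F,CXX,CXF numeric matrices.
#' @slot normalizationFactor positive scalar.
#' @slot auxCostQ scalar, `NA_real_` when no auxiliary states are present.
#' @exportClass CostSet
setClass("CostSet",
         slots = c(C0X = "matrix", C0F = "matrix",
                   CXX = "matrix", CXF = "matrix",
                   normalizationFactor = "numeric",
                   auxCostQ = "numeric"))

setValidity("CostSet", function(object) {
    msgs <- character()
    mats <- list(object@C0X, object@C0F, object@CXX, object@CXF)
    for (m in mats) {
        if (length(m) && (!all(is.finite(m)) || any(m < 0))) {
            msgs <- c(msgs, "cost entries must be finite and >= 0")
            break
        }
    }
    n <- ncol(object@C0X)
    if (nrow(object@CXX) != n || ncol(object@CXX) != n)
        msgs <- c(msgs, "CXX must be square with ncol(C0X) rows")
    if (nrow(object@C0F) != nrow(object@C0X))
        msgs <- c(msgs, "C0F and C0X must agree on the number of initial cells")
    if (nrow(object@CXF) != n)
        msgs <- c(msgs, "CXF must have one row per intermediate cell")
    if (ncol(object@CXF) != ncol(object@C0F))
        msgs <- c(msgs, "CXF and C0F must agree on the number of terminal cells")
    if (length(object@normalizationFactor) != 1L ||
        !is.finite(object@normalizationFactor) ||
        object@normalizationFactor <= 0)
        msgs <- c(msgs, "normalizationFactor must be a positive scalar")
    if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## MsotConfig
## ---------------------------------------------------------------------------

#' Solver configuration
#'
#' Parameters of the multistage transport solve.  `nStages` is the number of
#' transport stages `T` (stage indices run `0 .. T-1`, i.e. `T - 1`
#' intermediate transport steps).  `epsilonStart` is the entropic
#' regularization of the first proximal round; after `k` proximal rounds the
#' effective regularization is `epsilonStart / k`.
#'
#' @slot nStages integer, number of transport stages `T`.
#' @slot epsilonStart positive scalar entropic regularization.
#' @slot proxIters integer >= 1, outer proximal-point rounds.
#' @slot tolTau positive convergence tolerance on dual updates and
#'   constraint deviations.
#' @slot maxInnerIters cap on Sinkhorn sweeps per proximal round.
#' @slot auxCostQ scalar auxiliary cost (`NA` disables the extension).
#' @slot seed integer seed recorded for provenance.
#' @slot logDomain logical; use log-domain stabilized updates.
#' @exportClass MsotConfig
setClass("MsotConfig",
         slots = c(nStages = "integer",
                   epsilonStart = "numeric",
                   proxIters = "integer",
                   tolTau = "numeric",
                   maxInnerIters = "integer",
                   auxCostQ = "numeric",
                   seed = "integer",
                   logDomain = "logical"))

setValidity("MsotConfig", function(object) {
    msgs <- character()
    if (object@nStages < 2L)
        msgs <- c(msgs, "nStages must be >= 2")
    if (!is.finite(object@epsilonStart) || object@epsilonStart <= 0)
        msgs <- c(msgs, "epsilonStart must be > 0")
    if (object@proxIters < 1L)
        msgs <- c(msgs, "proxIters must be >= 1")
    if (!is.finite(object@tolTau) || object@tolTau <= 0)
        msgs <- c(msgs, "tolTau must be > 0")
    if (object@maxInnerIters < 1L)
        msgs <- c(msgs, "maxInnerIters must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' Create a solver configuration
#'
#' Defaults follow the settings used for expression data throughout the
#' package: `T - 1 = 20` intermediate transport steps, tolerance `1e-4`,
#' and a starting regularization of 0.05 lowered tenfold by the proximal
#' scheme (effective epsilon 0.005 on median-normalized costs).  For small
#' two-dimensional examples `nStages = 11` is the customary choice.
#'
#' @param nStages number of transport stages `T`.
#' @param epsilonStart starting entropic regularization.
#' @param proxIters number of outer proximal rounds; the effective
#'   regularization after the last round is `epsilonStart / proxIters`.
#' @param tol convergence tolerance (maximum over dual-variable updates and
#'   absolute constraint deviations).
#' @param maxInnerIters cap on Sinkhorn sweeps per proximal round.
#' @param auxCostQ fixed cost of transporting mass to an auxiliary state,
#'   on the median-normalized cost scale; `NA` disables auxiliary states.
#' @param seed integer seed recorded in reports.
#' @param logDomain use log-domain (stabilized) updates.
#'
#' @return An [MsotConfig-class].
#' @examples
#' msotConfig(nStages = 11, proxIters = 5)
#' @export
msotConfig <- function(nStages = 21L, epsilonStart = 0.05, proxIters = 10L,
                       tol = 1e-4, maxInnerIters = 50000L,
                       auxCostQ = NA_real_, seed = 0L, logDomain = FALSE) {
    new("MsotConfig", nStages = as.integer(nStages),
        epsilonStart = epsilonStart, proxIters = as.integer(proxIters),
        tolTau = tol, maxInnerIters = as.integer(maxInnerIters),
        auxCostQ = auxCostQ, seed = as.integer(seed), logDomain = logDomain)
}

## ---------------------------------------------------------------------------
## StagePlans
## ---------------------------------------------------------------------------

#' Stagewise transport plans
#'
#' The solver's output: nonnegative transport plans for every stage.
#' `Mtilde[[s]]` carries mass that continues in the system at stage
#' `t = s - 1` (the first plan is initial-to-intermediate, the rest
#' intermediate-to-intermediate); `Mhat[[s]]` carries mass exiting to the
#' terminal tier at stage `t = s - 1`.  All latent marginals are derived row
#' or column sums; see [muTilde()], [muHat()] and [nuHat()].
#'
#' @slot Mtilde list of `T - 1` matrices (n0 x n, then n x n).
#' @slot Mhat list of `T` matrices (n0 x nF, then n x nF).
#' @slot nStages integer `T`.
#' @exportClass StagePlans
setClass("StagePlans",
         slots = c(Mtilde = "list", Mhat = "list", nStages = "integer"))

setValidity("StagePlans", function(object) {
    msgs <- character()
    Tn <- object@nStages
    n <- if (length(object@Mtilde)) ncol(object@Mtilde[[1L]]) else 0L
    if (n > 0L && length(object@Mtilde) != Tn - 1L)
        msgs <- c(msgs, "Mtilde must hold T - 1 plans")
    if (length(object@Mhat) != (if (n > 0L) Tn else 1L))
        msgs <- c(msgs, "Mhat must hold T plans (1 when no intermediates)")
    for (m in c(object@Mtilde, object@Mhat)) {
        if (!all(is.finite(m)) || any(m < 0)) {
            msgs <- c(msgs, "plan entries must be finite and >= 0")
            break
        }
    }
    if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## SolveReport
## ---------------------------------------------------------------------------

#' Convergence report of a multistage transport solve
#'
#' @slot converged logical.
#' @slot innerIterations integer vector: Sinkhorn sweeps per proximal round.
#' @slot proxStepsDone integer.
#' @slot finalResidual maximum over dual-variable updates and absolute
#'   constraint deviations at termination.
#' @slot transportCost total linear transport cost
#'   `sum_t <Ctilde_t, Mtilde_t> + sum_t <Chat_t, Mhat_t>`.
#' @slot effectiveEpsilon `epsilonStart / proxStepsDone`.
#' @exportClass SolveReport
setClass("SolveReport",
         slots = c(converged = "logical",
                   innerIterations = "integer",
                   proxStepsDone = "integer",
                   finalResidual = "numeric",
                   transportCost = "numeric",
                   effectiveEpsilon = "numeric"))

## ---------------------------------------------------------------------------
## TransitionModel
## ---------------------------------------------------------------------------

#' Stage-aggregated absorbing Markov chain
#'
#' `A` sums the transported mass between every cell pair over all stages and
#' both plan families; `P` row-normalizes the transient rows of `A` and makes
#' every terminal cell absorbing (`P[j, j] = 1`).
#'
#' @slot P row-stochastic matrix over all modelled cells.
#' @slot A the unnormalized aggregated mass matrix.
#' @slot cellIds character vector naming rows/columns.
#' @slot terminal integer indices of the absorbing (terminal) cells.
#' @exportClass TransitionModel
setClass("TransitionModel",
         slots = c(P = "matrix", A = "matrix",
                   cellIds = "character", terminal = "integer"))

setValidity("TransitionModel", function(object) {
    msgs <- character()
    N <- length(object@cellIds)
    if (nrow(object@P) != N || ncol(object@P) != N)
        msgs <- c(msgs, "P must be square over cellIds")
    rs <- rowSums(object@P)
    if (length(rs) && max(abs(rs - 1)) > 1e-9)
        msgs <- c(msgs, "rows of P must sum to 1")
    if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## ClonalReference
## ---------------------------------------------------------------------------

#' Clonal-sister reference fate distributions
#'
#' For every eligible early cell (an early-time cell with at least one
#' fate-annotated clonal sister at a later time), the empirical distribution
#' of its sisters' fates.  Used as proxy ground truth by the benchmark
#' metrics.
#'
#' @slot cellIds early-time cell identifiers (all candidates).
#' @slot ref matrix, one row per candidate cell, one column per fate class;
#'   rows of ineligible cells are `NA`.
#' @slot eligible logical vector parallel to `cellIds`.
#' @exportClass ClonalReference
setClass("ClonalReference",
         slots = c(cellIds = "character", ref = "matrix",
                   eligible = "logical"))

## ---------------------------------------------------------------------------
## GroundTruth (synthetic data)
## ---------------------------------------------------------------------------

#' Ground truth of a synthetic branching snapshot
#'
#' @slot s numeric arc-length fraction along the skeleton in `[0, 1]` (true
#'   developmental time); `NA` for injected outliers.
#' @slot arm character arm label per cell (`"trunk"` for trunk cells, `NA`
#'   for outliers).
#' @slot outlier logical mask.
#' @exportClass GroundTruth
setClass("GroundTruth",
         slots = c(s = "numeric", arm = "character", outlier = "logical"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "Snapshot", function(object) {
    cat(sprintf("Snapshot: %d cells x %d %s\n",
                nrow(object@values), ncol(object@values),
                if (object@isEmbedding) "dims (embedding)" else "features"))
    if (ncol(object@meta))
        cat("  meta columns:", paste(colnames(object@meta), collapse = ", "),
            "\n")
})

setMethod("show", "StatePartition", function(object) {
    cat(sprintf("StatePartition: n0 = %d, n = %d, nF = %d%s\n",
                length(object@X0), length(object@X), length(object@XF),
                if (object@auxEnabled) " (auxiliary states enabled)" else ""))
    cat("  fate classes:", paste(object@fateClasses, collapse = ", "), "\n")
})

setMethod("show", "CostSet", function(object) {
    cat(sprintf(paste0("CostSet: n0 = %d, n = %d, nF = %d; ",
                       "normalizationFactor = %.4g%s\n"),
                nrow(object@C0X), ncol(object@C0X), ncol(object@C0F),
                object@normalizationFactor,
                if (is.na(object@auxCostQ)) ""
                else sprintf("; auxCostQ = %.3g", object@auxCostQ)))
})

setMethod("show", "MsotConfig", function(object) {
    cat(sprintf(paste0("MsotConfig: T = %d stages, epsilonStart = %.3g, ",
                       "proxIters = %d (effective eps %.3g), tol = %.1e\n"),
                object@nStages, object@epsilonStart, object@proxIters,
                object@epsilonStart / object@proxIters, object@tolTau))
})

setMethod("show", "StagePlans", function(object) {
    cat(sprintf("StagePlans over T = %d stages (%d continuing, %d exiting plans)\n",
                object@nStages, length(object@Mtilde), length(object@Mhat)))
})

setMethod("show", "SolveReport", function(object) {
    cat(sprintf(paste0("SolveReport: converged = %s after %d proximal rounds ",
                       "(%s sweeps), residual = %.2e\n",
                       "  transport cost = %.6g, effective epsilon = %.3g\n"),
                object@converged, object@proxStepsDone,
                paste(object@innerIterations, collapse = "+"),
                object@finalResidual, object@transportCost,
                object@effectiveEpsilon))
})

setMethod("show", "TransitionModel", function(object) {
    cat(sprintf("TransitionModel: %d cells, %d absorbing\n",
                length(object@cellIds), length(object@terminal)))
})

setMethod("show", "ClonalReference", function(object) {
    cat(sprintf("ClonalReference: %d candidate cells, %d eligible, classes: %s\n",
                length(object@cellIds), sum(object@eligible),
                paste(colnames(object@ref), collapse = ", ")))
})
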