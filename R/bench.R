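## Baseline predictor and lineage-tracing benchmark metrics.

#' Inverse-distance-weighted baseline fate predictor
#'
#' A naive reference predictor not based on optimal transport: for each
#' cell, the distance to a fate class is the minimum Euclidean distance to
#' any of that class's terminal cells, and the predicted fate probabilities
#' are proportional to the inverse distances raised to `power`.  A cell at
#' zero distance from a class gets the indicator of that class (uniform
#' over classes when several are at distance zero).
#'
#' @param embedding a [Snapshot-class] with coordinates.
#' @param partition a [StatePartition-class] over the same cells.
#' @param power inverse-distance exponent, `> 0` (default 2, consistent
#'   with squared-distance transition costs).
#' @return Matrix, cells x fate classes, rows summing to 1.
#' @export
idwFates <- function(embedding, partition, power = 2) {
    stopifnot(is(embedding, "Snapshot"), is(partition, "StatePartition"),
              power > 0)
    classes <- partition@fateClasses
    idx <- match(partition@cellIds, embedding@cellIds)
    if (anyNA(idx))
        stop("cells missing from the embedding: ",
             paste(partition@cellIds[is.na(idx)], collapse = ", "))
    co <- embedding@values[idx, , drop = FALSE]
    D <- vapply(classes, function(cl) {
        sel <- partition@XF[partition@fateOf == cl]
        if (!length(sel)) stop("fate class '", cl, "' has no terminal cells")
        d2 <- sqDist(co, co[sel, , drop = FALSE])
        sqrt(apply(d2, 1L, min))
    }, numeric(length(idx)))
    Fmat <- matrix(0, nrow(D), ncol(D),
                   dimnames = list(partition@cellIds, classes))
    zero <- D == 0
    hasZero <- rowSums(zero) > 0
    Fmat[hasZero, ] <- zero[hasZero, , drop = FALSE] /
        rowSums(zero[hasZero, , drop = FALSE])
    if (any(!hasZero)) {
        W <- D[!hasZero, , drop = FALSE]^(-power)
        Fmat[!hasZero, ] <- W / rowSums(W)
    }
    Fmat
}

#' Clonal-sister reference fate distributions
#'
#' For every cell at the earliest time point, gathers its same-clone cells
#' at the later time points that carry a fate annotation and returns the
#' empirical frequency of those sister fates.  Early cells without any
#' annotated sister are ineligible and carry no distribution.
#'
#' @param meta `data.frame` with columns `cell_id`, `clone_id`,
#'   `time_label`, `fate_annotation` (`NA` allowed for unannotated cells).
#' @param earlyTime time label of the evaluated (early) cells.
#' @param lateTimes time labels at which sisters are observed.
#' @param classes fate-class vocabulary, in declaration order.
#' @return A [ClonalReference-class].
#' @export
clonalReference <- function(meta, earlyTime, lateTimes, classes) {
    need <- c("cell_id", "clone_id", "time_label", "fate_annotation")
    if (!all(need %in% colnames(meta)))
        stop("meta must have columns: ", paste(need, collapse = ", "))
    ann <- meta$fate_annotation
    bad <- setdiff(stats::na.omit(unique(ann)), classes)
    if (length(bad))
        stop("unknown fate annotation(s): ", paste(bad, collapse = ", "))
    early <- meta[meta$time_label == earlyTime & !is.na(meta$clone_id), ,
                  drop = FALSE]
    late <- meta[meta$time_label %in% lateTimes & !is.na(ann) &
                 !is.na(meta$clone_id), , drop = FALSE]
    ref <- matrix(NA_real_, nrow(early), length(classes),
                  dimnames = list(early$cell_id, classes))
    eligible <- logical(nrow(early))
    for (i in seq_len(nrow(early))) {
        sis <- late$fate_annotation[late$clone_id == early$clone_id[i] &
                                    late$cell_id != early$cell_id[i]]
        if (length(sis)) {
            counts <- table(factor(sis, levels = classes))
            ref[i, ] <- as.numeric(counts) / sum(counts)
            eligible[i] <- TRUE
        }
    }
    new("ClonalReference", cellIds = as.character(early$cell_id),
        ref = ref, eligible = eligible)
}

#' Total variation distance between two fate distributions
#'
#' Half the L1 distance: `0.5 * sum_c |p_c - q_c|`, in `[0, 1]`.
#'
#' @param p,q probability vectors over the same (named, if named) support.
#' @return Scalar in `[0, 1]`.
#' @export
tvDistance <- function(p, q) {
    if (length(p) != length(q))
        stop("distributions must share the same support")
    if (!is.null(names(p)) && !is.null(names(q)) &&
        !identical(names(p), names(q)))
        stop("distributions must share the same support")
    if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
        stop("inputs must sum to 1")
    0.5 * sum(abs(p - q))
}

## Internal: align predictions with eligible reference cells.
.alignPredRef <- function(pred, ref) {
    stopifnot(is(ref, "ClonalReference"))
    cells <- ref@cellIds[ref@eligible]
    if (!length(cells)) stop("no eligible reference cells")
    miss <- setdiff(cells, rownames(pred))
    if (length(miss))
        stop("predictions missing for cells: ",
             paste(utils::head(miss, 5L), collapse = ", "))
    classes <- colnames(ref@ref)
    if (!all(classes %in% colnames(pred)))
        stop("prediction classes do not cover the reference classes")
    list(pred = pred[cells, classes, drop = FALSE],
         ref = ref@ref[cells, classes, drop = FALSE],
         cells = cells, classes = classes)
}

#' Dominant fate accuracy against clonal references
#'
#' Fraction of eligible cells whose highest-probability predicted fate
#' equals the most common fate among their clonal sisters.  Prediction
#' ties break by class declaration order; a reference with tied modes
#' counts as correct when the prediction matches any tied mode.
#'
#' @param pred matrix of predicted fate probabilities (rows named by cell).
#' @param ref a [ClonalReference-class].
#' @return Fraction in `[0, 1]`.
#' @export
dominantFateAccuracy <- function(pred, ref) {
    al <- .alignPredRef(pred, ref)
    hit <- vapply(seq_along(al$cells), function(i) {
        top <- which.max(al$pred[i, ])
        modes <- which(al$ref[i, ] == max(al$ref[i, ]))
        top %in% modes
    }, logical(1L))
    mean(hit)
}

#' Total fate accuracy against clonal references
#'
#' A cell with `k` distinct observed sister fates is correct when those
#' `k` fates are exactly the model's `k` highest-probability classes
#' (prediction ties break by class declaration order).
#'
#' @inheritParams dominantFateAccuracy
#' @return Fraction in `[0, 1]`.
#' @export
totalFateAccuracy <- function(pred, ref) {
    al <- .alignPredRef(pred, ref)
    hit <- vapply(seq_along(al$cells), function(i) {
        obs <- which(al$ref[i, ] > 0)
        k <- length(obs)
        topk <- order(-al$pred[i, ], seq_along(al$classes))[seq_len(k)]
        setequal(obs, topk)
    }, logical(1L))
    mean(hit)
}

#' Threshold sweep of exact fate-set assignment
#'
#' For each threshold `delta`, a cell is assigned the fates whose predicted
#' probability strictly exceeds `delta`; the assignment is correct only if
#' it equals the cell's observed sister-fate set exactly.
#'
#' @inheritParams dominantFateAccuracy
#' @param grid thresholds in `[0, 1]` (default 101 equally spaced values).
#' @return `data.frame(delta, fraction_correct)`.
#' @export
deltaSweep <- function(pred, ref, grid = seq(0, 1, length.out = 101L)) {
    stopifnot(all(grid >= 0), all(grid <= 1))
    al <- .alignPredRef(pred, ref)
    obs <- lapply(seq_along(al$cells), function(i) which(al$ref[i, ] > 0))
    frac <- vapply(grid, function(delta) {
        mean(vapply(seq_along(al$cells), function(i) {
            setequal(which(al$pred[i, ] > delta), obs[[i]])
        }, logical(1L)))
    }, numeric(1L))
    data.frame(delta = grid, fraction_correct = frac)
}

#' Accuracy of dominant predictions against per-cell annotations
#'
#' Fraction of annotated cells whose highest-probability predicted fate
#' equals the annotation (ties break by class declaration order).
#'
#' @param pred matrix of predicted fate probabilities (rows named by cell).
#' @param labels named character vector of fate annotations (`NA` entries
#'   are dropped).
#' @return Fraction in `[0, 1]`.
#' @export
annotationAccuracy <- function(pred, labels) {
    labels <- labels[!is.na(labels)]
    if (!length(labels)) stop("no annotated cells")
    bad <- setdiff(unique(labels), colnames(pred))
    if (length(bad))
        stop("annotation(s) outside the class set: ",
             paste(bad, collapse = ", "))
    miss <- setdiff(names(labels), rownames(pred))
    if (length(miss))
        stop("predictions missing for cells: ",
             paste(utils::head(miss, 5L), collapse = ", "))
    top <- colnames(pred)[apply(pred[names(labels), , drop = FALSE], 1L,
                                which.max)]
    mean(top == labels)
}
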