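## Downstream analysis of stagewise transport plans.

.auxIds <- c("aux_initial", "aux_intermediate", "aux_terminal")

.realCells <- function(partition) {
    if (partition@auxEnabled)
        setdiff(partition@cellIds, .auxIds)
    else partition@cellIds
}

#' Per-cell probability distribution over transport stages
#'
#' The more mass a cell transports in a stage, the more likely it is to
#' transition in that stage.  Initial cells transport only at stage 0;
#' an intermediate cell's share at stage `t` is proportional to its total
#' outgoing mass (continuing plus exiting) at that stage; a terminal cell's
#' share is proportional to the mass it receives at each stage.  Rows are
#' normalized to 1.
#'
#' @param plans a [StagePlans-class] from a converged solve.
#' @param partition the matching [StatePartition-class].
#' @return Matrix, cells x stages (`stage_0 .. stage_{T-1}`), rows summing
#'   to 1.
#' @export
stageDistributions <- function(plans, partition) {
    stopifnot(is(plans, "StagePlans"), is(partition, "StatePartition"))
    N <- length(partition@cellIds)
    Tn <- plans@nStages
    S1 <- length(plans@Mtilde)
    D <- matrix(0, N, Tn,
                dimnames = list(partition@cellIds,
                                paste0("stage_", seq_len(Tn) - 1L)))
    D[partition@X0, 1L] <- 1
    if (length(partition@X)) {
        for (t in seq_len(Tn - 1L)) {
            out <- rowSums(plans@Mhat[[t + 1L]])
            if (t + 1L <= S1) out <- out + rowSums(plans@Mtilde[[t + 1L]])
            D[partition@X, t + 1L] <- out
        }
    }
    for (t in seq_len(length(plans@Mhat)) - 1L)
        D[partition@XF, t + 1L] <- colSums(plans@Mhat[[t + 1L]])
    tot <- rowSums(D)
    if (any(tot <= 0))
        stop("cell(s) with zero total throughput: ",
             paste(utils::head(partition@cellIds[tot <= 0], 5L),
                   collapse = ", "),
             " (plans do not come from a converged solve)")
    D / tot
}

#' Pseudotime from stage distributions
#'
#' The raw mean transport stage of each cell is the expectation of its
#' stage distribution; terminal cells, whose distribution is over incoming
#' mass, are shifted by +1 so that a terminal receiving at stage `t` ranks
#' after the cells transporting at stage `t`.  Pseudotime is the min-max
#' normalization of the raw values to `[0, 1]` (0 when all raw values
#' coincide).  Auxiliary states are excluded from the result.
#'
#' @param stages matrix from [stageDistributions()].
#' @param partition the matching [StatePartition-class].
#' @return `data.frame(cell_id, raw_mean_stage, pseudotime)` in snapshot
#'   order, one row per non-auxiliary cell.
#' @export
msotPseudotime <- function(stages, partition) {
    stopifnot(is(partition, "StatePartition"))
    Tn <- ncol(stages)
    raw <- drop(stages %*% (seq_len(Tn) - 1L))
    raw[partition@XF] <- raw[partition@XF] + 1
    keep <- match(.realCells(partition), partition@cellIds)
    raw <- raw[keep]
    rng <- range(raw)
    pt <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
          else rep(0, length(raw))
    data.frame(cell_id = partition@cellIds[keep],
               raw_mean_stage = unname(raw),
               pseudotime = unname(pt),
               stringsAsFactors = FALSE)
}

#' Stage-aggregated transition model
#'
#' Sums, over all stages and both plan families, the mass transported
#' between every ordered cell pair, then row-normalizes the transient rows
#' into a stationary absorbing Markov chain in which every terminal cell is
#' absorbing.
#'
#' @param plans a [StagePlans-class].
#' @param partition the matching [StatePartition-class].
#' @return A [TransitionModel-class].
#' @export
aggregateTransitions <- function(plans, partition) {
    stopifnot(is(plans, "StagePlans"), is(partition, "StatePartition"))
    N <- length(partition@cellIds)
    S1 <- length(plans@Mtilde)
    A <- matrix(0, N, N,
                dimnames = list(partition@cellIds, partition@cellIds))
    if (S1 > 0L) {
        A[partition@X0, partition@X] <- plans@Mtilde[[1L]]
        XX <- 0
        XFm <- 0
        for (s in seq_len(S1)) {
            if (s >= 2L) XX <- XX + plans@Mtilde[[s]]
            XFm <- XFm + plans@Mhat[[s + 1L]]
        }
        if (S1 >= 2L) A[partition@X, partition@X] <- XX
        A[partition@X, partition@XF] <- XFm
    }
    A[partition@X0, partition@XF] <- plans@Mhat[[1L]]
    P <- A
    trans <- c(partition@X0, partition@X)
    tot <- rowSums(A[trans, , drop = FALSE])
    if (any(tot <= 0))
        stop("transient cell(s) with zero outgoing mass: ",
             paste(utils::head(partition@cellIds[trans][tot <= 0], 5L),
                   collapse = ", "))
    P[trans, ] <- A[trans, , drop = FALSE] / tot
    P[partition@XF, ] <- 0
    P[cbind(partition@XF, partition@XF)] <- 1
    new("TransitionModel", P = P, A = A, cellIds = partition@cellIds,
        terminal = partition@XF)
}

#' Absorption (fate) probabilities under the aggregated chain
#'
#' Groups the terminal cells into fate classes and solves the linear
#' absorption system `(I - P_tt) F = P_tf Z` for the transient cells
#' (`Z` the terminal-to-class indicator), by LU solves rather than explicit
#' inversion.  A terminal cell's row is the indicator of its own class.
#'
#' @param model a [TransitionModel-class].
#' @param partition the matching [StatePartition-class].
#' @return Matrix, cells x fate classes (including `"unknown"` when
#'   auxiliary states are enabled); rows sum to 1.
#' @export
fateProbabilities <- function(model, partition) {
    stopifnot(is(model, "TransitionModel"), is(partition, "StatePartition"))
    P <- model@P
    trans <- c(partition@X0, partition@X)
    XF <- partition@XF
    classes <- partition@fateClasses
    Z <- outer(partition@fateOf, classes, "==") * 1
    Ptt <- P[trans, trans, drop = FALSE]
    Ptf <- P[trans, XF, drop = FALSE]
    ## reachability check: every transient cell must reach some terminal
    reach <- rowSums(Ptf) > 0
    repeat {
        grown <- reach | (drop(Ptt %*% reach) > 0)
        if (identical(grown, reach)) break
        reach <- grown
    }
    if (!all(reach))
        stop("absorbing-chain error: transient cell(s) cannot reach any ",
             "terminal state: ",
             paste(utils::head(partition@cellIds[trans][!reach], 5L),
                   collapse = ", "))
    Ftrans <- solve(diag(nrow(Ptt)) - Ptt, Ptf %*% Z)
    Fmat <- matrix(0, length(partition@cellIds), length(classes),
                   dimnames = list(partition@cellIds, classes))
    Fmat[trans, ] <- Ftrans
    Fmat[XF, ] <- Z
    Fmat
}

#' Shannon entropy of fate probabilities
#'
#' `H_i = -sum_c F_ic log F_ic` (with `0 log 0 = 0`), a per-cell measure of
#' multipotency: 0 for full commitment, `log L` for indifference among `L`
#' fates.  The mean is taken over non-terminal cells, excluding auxiliary
#' states.
#'
#' @param fates matrix from [fateProbabilities()].
#' @param partition the matching [StatePartition-class].
#' @param base logarithm base (natural log by default).
#' @return `list(perCell = named numeric, meanNonTerminal = scalar)`.
#' @export
fateEntropy <- function(fates, partition, base = exp(1)) {
    stopifnot(is(partition, "StatePartition"))
    H <- apply(fates, 1L, function(p) {
        p <- p[p > 0]
        -sum(p * log(p, base = base))
    })
    nonterm <- setdiff(.realCells(partition),
                       partition@cellIds[partition@XF])
    list(perCell = H, meanNonTerminal = mean(H[nonterm]))
}

#' Flag outlier cells by their "unknown fate" probability
#'
#' Requires the auxiliary-state extension: a cell is flagged when its
#' probability of absorption in the auxiliary terminal state (the
#' `"unknown"` fate class) exceeds the threshold.
#'
#' @param fates matrix from [fateProbabilities()] containing an `"unknown"`
#'   column.
#' @param threshold strict flagging threshold (default 0.5).
#' @return Named logical vector over non-auxiliary cells.
#' @export
flagOutliers <- function(fates, threshold = 0.5) {
    if (!("unknown" %in% colnames(fates)))
        stop("no 'unknown' fate class: run with auxiliary states enabled")
    keep <- setdiff(rownames(fates), .auxIds)
    fates[keep, "unknown"] > threshold
}

#' Gate cells on their fate-probability profile
#'
#' Returns the cells committed to every target fate above `minTarget` and
#' to every other fate below `maxOther` (strict comparisons).  The default
#' thresholds (10% / 1%) select cells with specific bipotent commitment,
#' e.g. candidate basophil-mast cell progenitors when gating on those two
#' fates.
#'
#' @param fates matrix from [fateProbabilities()].
#' @param targetFates character vector of fate classes.
#' @param minTarget lower threshold applied to every target fate.
#' @param maxOther upper threshold applied to every other fate.
#' @return Character vector of gated cell ids.
#' @export
gateCells <- function(fates, targetFates, minTarget = 0.10,
                      maxOther = 0.01) {
    stopifnot(length(targetFates) >= 1L,
              minTarget >= 0, minTarget <= 1, maxOther >= 0, maxOther <= 1)
    bad <- setdiff(targetFates, colnames(fates))
    if (length(bad))
        stop("unknown fate class(es): ", paste(bad, collapse = ", "))
    others <- setdiff(colnames(fates), targetFates)
    keep <- setdiff(rownames(fates), .auxIds)
    Fm <- fates[keep, , drop = FALSE]
    ok <- rowSums(Fm[, targetFates, drop = FALSE] > minTarget) ==
              length(targetFates)
    if (length(others))
        ok <- ok & rowSums(Fm[, others, drop = FALSE] < maxOther) ==
                       length(others)
    rownames(Fm)[ok]
}
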