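## Core preprocessing, cost construction and partitioning.

#' Library-size normalize and log-transform raw counts
#'
#' Divides each cell's counts by its total, rescales to the median total
#' count across cells, and applies `log(x + 1)`.  This is the minimal
#' standard recipe ahead of PCA; highly-variable-gene filtering is
#' deliberately not applied (supply a pre-filtered matrix if wanted).
#'
#' @param snapshot a [Snapshot-class] carrying raw counts
#'   (`isEmbedding = FALSE`).
#' @return A new `Snapshot` with transformed values; the input is not
#'   modified.
#' @examples
#' sn <- Snapshot(matrix(rpois(30, 10), nrow = 5))
#' preprocessCounts(sn)
#' @export
preprocessCounts <- function(snapshot) {
    stopifnot(is(snapshot, "Snapshot"))
    if (isTRUE(snapshot@isEmbedding))
        stop("preprocessCounts() expects raw counts, not an embedding")
    v <- snapshot@values
    if (!all(is.finite(v)) || any(v < 0))
        stop("count matrix entries must be finite and >= 0")
    totals <- rowSums(v)
    if (any(totals == 0))
        stop("cells with zero total counts cannot be normalized: ",
             paste(snapshot@cellIds[totals == 0], collapse = ", "))
    sf <- totals / stats::median(totals)
    out <- log1p(v / sf)
    Snapshot(out, cellIds = snapshot@cellIds, isEmbedding = FALSE,
             meta = snapshot@meta)
}

#' Project a snapshot onto its leading principal components
#'
#' Centred (unscaled) PCA of the preprocessed expression matrix; the
#' default of 50 components is the customary dimensionality ahead of
#' squared-Euclidean transition costs.  Component signs are fixed so that
#' each loading vector's largest-magnitude entry is positive, making the
#' embedding reproducible across runs.
#'
#' @param snapshot a [Snapshot-class] (typically from [preprocessCounts()]).
#' @param nComponents number of components to keep.
#' @param seed integer recorded for provenance (the decomposition itself is
#'   deterministic).
#' @return A `Snapshot` with `isEmbedding = TRUE` and an
#'   `"explainedVariance"` attribute on its matrix.
#' @export
pcaEmbed <- function(snapshot, nComponents = 50L, seed = 0L) {
    stopifnot(is(snapshot, "Snapshot"))
    v <- snapshot@values
    nComponents <- as.integer(nComponents)
    if (nComponents < 1L || nComponents > min(dim(v)))
        stop("nComponents must be between 1 and min(cells, features)")
    pc <- stats::prcomp(v, center = TRUE, scale. = FALSE,
                        rank. = nComponents)
    flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
        w <- pc$rotation[, j]
        sign(w[which.max(abs(w))])
    }, numeric(1L))
    emb <- sweep(pc$x[, seq_len(nComponents), drop = FALSE], 2L, flip, "*")
    colnames(emb) <- paste0("dim_", seq_len(nComponents))
    attr(emb, "explainedVariance") <- pc$sdev[seq_len(nComponents)]^2
    Snapshot(emb, cellIds = snapshot@cellIds, isEmbedding = TRUE,
             meta = snapshot@meta)
}

#' Squared-Euclidean transition costs between cell tiers
#'
#' Builds the four cost blocks (initial to intermediate, initial to
#' terminal, intermediate to intermediate, intermediate to terminal) as
#' squared Euclidean distances between embedding coordinates.  The
#' intermediate-to-intermediate diagonal is exactly zero, so mass may stay
#' at the same cell across stages at no cost.
#'
#' @param embedding a [Snapshot-class] with `isEmbedding = TRUE` (or any
#'   coordinate matrix snapshot).
#' @param partition a [StatePartition-class] over the same cells.
#' @return A [CostSet-class] (unnormalized: `normalizationFactor = 1`).
#' @export
computeCosts <- function(embedding, partition) {
    stopifnot(is(embedding, "Snapshot"), is(partition, "StatePartition"))
    idx <- match(partition@cellIds, embedding@cellIds)
    if (anyNA(idx))
        stop("cells missing from the embedding: ",
             paste(partition@cellIds[is.na(idx)], collapse = ", "))
    co <- embedding@values[idx, , drop = FALSE]
    E0 <- co[partition@X0, , drop = FALSE]
    EX <- co[partition@X, , drop = FALSE]
    EF <- co[partition@XF, , drop = FALSE]
    CXX <- sqDist(EX, EX)
    diag(CXX) <- 0
    new("CostSet",
        C0X = sqDist(E0, EX), C0F = sqDist(E0, EF),
        CXX = CXX, CXF = sqDist(EX, EF),
        normalizationFactor = 1, auxCostQ = NA_real_)
}

#' Median-normalize a cost set
#'
#' Divides every entry of all four cost blocks by the median of their
#' pooled entries, putting the entropic regularization parameter on a
#' scale comparable across datasets.  The median divided out is recorded
#' in `normalizationFactor`.  Normalization must precede
#' [augmentAuxiliary()] (the fixed auxiliary cost is defined on the
#' normalized scale).
#'
#' @param costs a [CostSet-class].
#' @return A normalized `CostSet` whose pooled entry median is 1.
#' @export
normalizeCosts <- function(costs) {
    stopifnot(is(costs, "CostSet"))
    if (!is.na(costs@auxCostQ))
        stop("normalize costs before augmenting with auxiliary states")
    pooled <- c(costs@C0X, costs@C0F, costs@CXX, costs@CXF)
    med <- stats::median(pooled)
    if (!is.finite(med) || med <= 0)
        stop("degenerate cost set: pooled median is not positive")
    new("CostSet",
        C0X = costs@C0X / med, C0F = costs@C0F / med,
        CXX = costs@CXX / med, CXF = costs@CXF / med,
        normalizationFactor = costs@normalizationFactor * med,
        auxCostQ = NA_real_)
}

#' Split a snapshot into uniformly subsampled disjoint subsets
#'
#' Used to keep the solve within memory on large snapshots: each subset is
#' solved independently and the results pooled.  Initial cells and each
#' fate's terminal cells are dealt out in equal (plus/minus one) shares;
#' intermediate cells are split uniformly, with any remainder appended to
#' the last subset.
#'
#' @param snapshot a [Snapshot-class].
#' @param partition a [StatePartition-class] over the same cells.
#' @param k number of subsets.
#' @param seed integer; subsets are deterministic given the seed.
#' @return A list of `k` elements, each `list(snapshot =, partition =)`.
#' @export
partitionSubsets <- function(snapshot, partition, k, seed = 0L) {
    stopifnot(is(snapshot, "Snapshot"), is(partition, "StatePartition"))
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    if (length(partition@X0) < k)
        stop("fewer initial cells than subsets")
    for (cl in partition@fateClasses) {
        if (sum(partition@fateOf == cl) < k)
            stop("fate class '", cl, "' has fewer terminal cells than subsets")
    }
    if (partition@auxEnabled)
        stop("subset before augmenting with auxiliary states")
    dealEqual <- function(idx, k) {
        m <- length(idx)
        sizes <- rep(m %/% k, k)
        r <- m %% k
        if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
        split(idx, rep(seq_len(k), times = sizes))
    }
    dealRemainderLast <- function(idx, k) {
        m <- length(idx)
        sizes <- rep(m %/% k, k)
        sizes[k] <- sizes[k] + m %% k
        if (m == 0L) return(rep(list(integer()), k))
        split(idx, rep(seq_len(k), times = sizes))
    }
    withSeed(seed, {
        g0 <- dealEqual(sample(partition@X0), k)
        gF <- rep(list(integer()), k)
        for (cl in partition@fateClasses) {
            shares <- dealEqual(sample(partition@XF[partition@fateOf == cl]), k)
            for (i in seq_len(k)) gF[[i]] <- c(gF[[i]], shares[[i]])
        }
        gX <- dealRemainderLast(sample(partition@X), k)
        lapply(seq_len(k), function(i) {
            keep <- sort(c(g0[[i]], gX[[i]], gF[[i]]))
            ids <- partition@cellIds[keep]
            rows <- match(ids, snapshot@cellIds)
            sub <- Snapshot(snapshot@values[rows, , drop = FALSE],
                            cellIds = ids,
                            isEmbedding = snapshot@isEmbedding,
                            meta = snapshot@meta[rows, , drop = FALSE])
            fsel <- match(gF[[i]], partition@XF)
            part <- statePartition(ids,
                                   initial = partition@cellIds[g0[[i]]],
                                   terminal = partition@cellIds[gF[[i]]],
                                   fateOf = partition@fateOf[fsel],
                                   fateClasses = partition@fateClasses)
            list(snapshot = sub, partition = part)
        })
    })
}

#' Add auxiliary initial, intermediate and terminal states
#'
#' Extends the model with one artificial state per tier, reachable from any
#' real cell at the fixed cost `Q` (on the median-normalized cost scale).
#' Transitions among the auxiliary states themselves are free, so the
#' auxiliary channel forms a parallel process whose toll is `Q` per hop
#' from a real cell.  The auxiliary terminal state defines the fate class
#' `"unknown"`; cells strongly absorbed there are flagged as outliers by
#' [flagOutliers()].  Routing mass through the channel also bounds the
#' effective transition cost, stabilizing the solver against extreme
#' distances.
#'
#' @param costs a median-normalized [CostSet-class].
#' @param partition the matching [StatePartition-class].
#' @param Q fixed auxiliary transport cost, `> 0`; 3.25 is a conservative
#'   default for median-normalized single-cell data (values around 2 behave
#'   similarly).
#' @return `list(costs =, partition =)` with one auxiliary member appended
#'   to each tier.
#' @export
augmentAuxiliary <- function(costs, partition, Q = 3.25) {
    stopifnot(is(costs, "CostSet"), is(partition, "StatePartition"))
    if (!is.finite(Q) || Q <= 0) stop("auxiliary cost Q must be > 0")
    if (partition@auxEnabled) stop("auxiliary states already present")
    n0 <- nrow(costs@C0X); n <- ncol(costs@C0X); nF <- ncol(costs@C0F)
    padBlock <- function(M, rowCost, colCost, corner) {
        M2 <- rbind(cbind(M, rep(colCost, nrow(M))),
                    c(rep(rowCost, ncol(M)), corner))
        unname(M2)
    }
    C0X <- padBlock(costs@C0X, Q, Q, 0)
    C0F <- padBlock(costs@C0F, Q, Q, 0)
    CXX <- padBlock(costs@CXX, Q, Q, 0)
    CXF <- padBlock(costs@CXF, Q, Q, 0)
    auxIds <- c("aux_initial", "aux_intermediate", "aux_terminal")
    if (any(auxIds %in% partition@cellIds))
        stop("cell ids clash with reserved auxiliary state names")
    N <- length(partition@cellIds)
    part <- new("StatePartition",
                cellIds = c(partition@cellIds, auxIds),
                X0 = c(partition@X0, N + 1L),
                X = c(partition@X, N + 2L),
                XF = c(partition@XF, N + 3L),
                fateOf = c(partition@fateOf, "unknown"),
                fateClasses = c(partition@fateClasses, "unknown"),
                auxEnabled = TRUE)
    cs <- new("CostSet", C0X = C0X, C0F = C0F, CXX = CXX, CXF = CXF,
              normalizationFactor = costs@normalizationFactor,
              auxCostQ = Q)
    list(costs = cs, partition = part)
}
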