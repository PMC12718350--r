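## Seeded generators for branching 2D snapshots, outliers and clone labels.

#' Specification of a branching skeleton in the unit square
#'
#' @slot root,trunkEnd 2D points: start of the trunk and the branch point.
#' @slot armDirections matrix (arms x 2) of unit directions from the branch
#'   point.
#' @slot armLengths numeric arm lengths.
#' @slot armNames character arm (fate) labels, in declaration order.
#' @slot nCells,nInitial,nTerminalPerArm integer counts.
#' @slot noiseSd isotropic Gaussian noise standard deviation.
#' @slot seed integer seed.
#' @exportClass SkeletonSpec
setClass("SkeletonSpec",
         slots = c(root = "numeric", trunkEnd = "numeric",
                   armDirections = "matrix", armLengths = "numeric",
                   armNames = "character",
                   nCells = "integer", noiseSd = "numeric",
                   nInitial = "integer", nTerminalPerArm = "integer",
                   seed = "integer"))

setValidity("SkeletonSpec", function(object) {
    msgs <- character()
    tips <- .armTips(object)
    pts <- rbind(object@root, object@trunkEnd, tips)
    if (any(pts < 0) || any(pts > 1))
        msgs <- c(msgs, "skeleton points must lie inside the unit square")
    nArms <- nrow(object@armDirections)
    if (length(object@armLengths) != nArms ||
        length(object@armNames) != nArms)
        msgs <- c(msgs, "armDirections, armLengths and armNames must agree")
    if (object@noiseSd < 0)
        msgs <- c(msgs, "noiseSd must be >= 0")
    if (object@nCells < object@nInitial + nArms * object@nTerminalPerArm)
        msgs <- c(msgs, "nCells too small for the requested designations")
    if (nArms >= 2L) {
        dtip <- as.matrix(stats::dist(tips))
        diag(dtip) <- Inf
        ## arms must stay separable under the requested noise
        if (min(dtip) < 6 * object@noiseSd)
            msgs <- c(msgs, "arm tips too close for the requested noiseSd")
    }
    if (length(msgs)) msgs else TRUE
})

.armTips <- function(spec) {
    sweep(spec@armDirections, 1L, spec@armLengths, "*") +
        rep(spec@trunkEnd, each = nrow(spec@armDirections))
}

#' Create a branching-skeleton specification
#'
#' The default mimics a developmental process in the unit square: a trunk
#' rising from `(0.5, 0.05)` to `(0.5, 0.4)` and four arms of length 0.5
#' diverging toward the sides and upper corners, sampled by 400 cells with
#' noise 0.02, five designated initial cells at the root and five terminal
#' cells per arm tip.
#'
#' @param root,trunkEnd 2D points.
#' @param armDirections matrix of directions (rows are normalized).
#' @param armLengths arm lengths (recycled).
#' @param armNames fate labels per arm.
#' @param nCells,nInitial,nTerminalPerArm counts.
#' @param noiseSd isotropic Gaussian noise sd.
#' @param seed integer seed.
#' @return A [SkeletonSpec-class].
#' @export
skeletonSpec <- function(root = c(0.5, 0.05), trunkEnd = c(0.5, 0.4),
                         armDirections = rbind(c(-1, 0), c(-1, 1),
                                               c(1, 1), c(1, 0)),
                         armLengths = 0.5,
                         armNames = paste0("arm", seq_len(nrow(armDirections))),
                         nCells = 400L, noiseSd = 0.02,
                         nInitial = 5L, nTerminalPerArm = 5L, seed = 0L) {
    armDirections <- as.matrix(armDirections)
    armDirections <- armDirections / sqrt(rowSums(armDirections^2))
    armLengths <- rep_len(armLengths, nrow(armDirections))
    new("SkeletonSpec", root = as.numeric(root),
        trunkEnd = as.numeric(trunkEnd),
        armDirections = armDirections, armLengths = armLengths,
        armNames = as.character(armNames),
        nCells = as.integer(nCells), noiseSd = noiseSd,
        nInitial = as.integer(nInitial),
        nTerminalPerArm = as.integer(nTerminalPerArm),
        seed = as.integer(seed))
}

#' Generate a branching 2D snapshot with known ground truth
#'
#' Samples arc-length positions uniformly along the skeleton (trunk first,
#' then a uniformly chosen arm), adds isotropic Gaussian noise clipped to
#' the unit square, and designates the `nInitial` cells nearest the root as
#' initial states and the `nTerminalPerArm` cells nearest each arm tip as
#' that fate's terminal states.  Deterministic given the spec's seed.
#'
#' @param spec a [SkeletonSpec-class].
#' @return `list(snapshot = Snapshot, partition = StatePartition,
#'   truth = GroundTruth)`.  The snapshot's metadata repeats the ground
#'   truth columns (`s`, `arm`) for convenience.
#' @examples
#' sim <- makeBranchingSnapshot(skeletonSpec(nCells = 100, seed = 1))
#' table(sim$truth@arm)
#' @export
makeBranchingSnapshot <- function(spec) {
    stopifnot(is(spec, "SkeletonSpec"))
    nArms <- nrow(spec@armDirections)
    trunkVec <- spec@trunkEnd - spec@root
    trunkLen <- sqrt(sum(trunkVec^2))
    withSeed(spec@seed, {
        s <- stats::runif(spec@nCells)
        armPick <- sample.int(nArms, spec@nCells, replace = TRUE)
        totalLen <- trunkLen + spec@armLengths[armPick]
        arc <- s * totalLen
        onTrunk <- arc <= trunkLen
        pos <- matrix(0, spec@nCells, 2L)
        pos[onTrunk, ] <- rep(spec@root, each = sum(onTrunk)) +
            (arc[onTrunk] / trunkLen) %o% trunkVec
        if (any(!onTrunk)) {
            k <- which(!onTrunk)
            pos[k, ] <- rep(spec@trunkEnd, each = length(k)) +
                (arc[k] - trunkLen) * spec@armDirections[armPick[k], ,
                                                         drop = FALSE]
        }
        arm <- ifelse(onTrunk, "trunk", spec@armNames[armPick])
        noisy <- pos + matrix(stats::rnorm(2L * spec@nCells,
                                           sd = spec@noiseSd),
                              ncol = 2L)
        noisy <- pmin(pmax(noisy, 0), 1)
        ids <- sprintf("cell_%04d", seq_len(spec@nCells))
        dimnames(noisy) <- list(ids, c("dim_1", "dim_2"))

        dRoot <- sqrt(colSums((t(noisy) - spec@root)^2))
        X0 <- order(dRoot)[seq_len(spec@nInitial)]
        taken <- X0
        tips <- .armTips(spec)
        XF <- integer(); fates <- character()
        for (aIdx in seq_len(nArms)) {
            dTip <- sqrt(colSums((t(noisy) - tips[aIdx, ])^2))
            dTip[taken] <- Inf
            sel <- order(dTip)[seq_len(spec@nTerminalPerArm)]
            XF <- c(XF, sel); fates <- c(fates, rep(spec@armNames[aIdx],
                                                    spec@nTerminalPerArm))
            taken <- c(taken, sel)
        }
        meta <- data.frame(s = s, arm = arm, row.names = ids,
                           stringsAsFactors = FALSE)
        snapshot <- Snapshot(noisy, cellIds = ids, isEmbedding = TRUE,
                             meta = meta)
        partition <- statePartition(ids, initial = ids[X0],
                                    terminal = ids[XF], fateOf = fates,
                                    fateClasses = spec@armNames)
        truth <- new("GroundTruth", s = stats::setNames(s, ids),
                     arm = stats::setNames(arm, ids),
                     outlier = stats::setNames(rep(FALSE, spec@nCells), ids))
        list(snapshot = snapshot, partition = partition, truth = truth)
    })
}

#' Inject a compact far-displaced outlier cluster
#'
#' Appends `m` points in a small Gaussian cluster whose every point is at
#' Euclidean distance at least `displacement` from every original point
#' (the centroid is placed along a seeded random direction, beyond the
#' data's radius by `displacement` plus the cluster's own radius).
#' Outliers enter the partition as intermediate states and are marked in
#' the ground truth.
#'
#' @param snapshot a coordinate [Snapshot-class].
#' @param truth the matching [GroundTruth-class].
#' @param partition optional [StatePartition-class] to extend.
#' @param m number of outliers, `>= 1`.
#' @param displacement minimum distance from any outlier to any original
#'   point, `> 0`.
#' @param clusterSd spread of the outlier cluster.
#' @param seed integer seed.
#' @return `list(snapshot =, truth =, partition =)` (`partition` is `NULL`
#'   when not supplied).
#' @export
injectOutliers <- function(snapshot, truth, partition = NULL, m = 10L,
                           displacement = 3, clusterSd = 0.02, seed = 0L) {
    stopifnot(is(snapshot, "Snapshot"), is(truth, "GroundTruth"))
    m <- as.integer(m)
    if (m < 1L) stop("m must be >= 1")
    if (displacement <= 0) stop("displacement must be > 0")
    co <- snapshot@values
    center <- colMeans(co)
    R0 <- sqrt(max(rowSums(sweep(co, 2L, center)^2)))
    withSeed(seed, {
        theta <- stats::runif(1L, 0, 2 * pi)
        u <- c(cos(theta), sin(theta))
        offsets <- matrix(stats::rnorm(2L * m, sd = clusterSd), ncol = 2L)
        rad <- sqrt(max(rowSums(offsets^2)))
        centroid <- center + (R0 + displacement + rad) * u
        pts <- sweep(offsets, 2L, centroid, "+")
        ids <- sprintf("outlier_%03d", seq_len(m))
        rownames(pts) <- ids
        colnames(pts) <- colnames(co)
        vals <- rbind(co, pts)
        meta <- snapshot@meta
        if (ncol(meta)) {
            pad <- meta[rep(NA_integer_, m), , drop = FALSE]
            rownames(pad) <- ids
            meta <- rbind(meta, pad)
        }
        sn2 <- Snapshot(vals, cellIds = c(snapshot@cellIds, ids),
                        isEmbedding = snapshot@isEmbedding, meta = meta)
        tr2 <- new("GroundTruth",
                   s = c(truth@s, stats::setNames(rep(NA_real_, m), ids)),
                   arm = c(truth@arm, stats::setNames(rep(NA_character_, m),
                                                      ids)),
                   outlier = c(truth@outlier,
                               stats::setNames(rep(TRUE, m), ids)))
        p2 <- NULL
        if (!is.null(partition)) {
            p2 <- statePartition(
                cellIds(sn2),
                initial = partition@cellIds[partition@X0],
                terminal = partition@cellIds[partition@XF],
                fateOf = partition@fateOf,
                fateClasses = partition@fateClasses)
        }
        list(snapshot = sn2, truth = tr2, partition = p2)
    })
}

#' Simulate clonal lineage-tracing metadata
#'
#' Emulates a barcoding experiment on the synthetic snapshot: each clone
#' gets a founder among early cells (skeleton position `s` below
#' `earlyCutoff`, labelled time `"early"`) and `sistersPerClone` sisters
#' among late arm cells (`s` above `lateCutoff`, labelled `"late"`) with
#' the sister's arm as its fate annotation.  Founders inside an arm draw
#' sisters only from that arm; trunk founders draw from all arms.  Sisters
#' are drawn without replacement across clones.
#'
#' @param snapshot the [Snapshot-class] the truth refers to.
#' @param truth a [GroundTruth-class].
#' @param nClones number of clones.
#' @param sistersPerClone sisters per clone.
#' @param seed integer seed.
#' @param earlyCutoff,lateCutoff skeleton-position cutoffs.
#' @return `data.frame(cell_id, clone_id, time_label, fate_annotation)`
#'   (annotation `NA` on founder rows).
#' @export
simulateClones <- function(snapshot, truth, nClones = 30L,
                           sistersPerClone = 3L, seed = 0L,
                           earlyCutoff = 0.3, lateCutoff = 0.7) {
    stopifnot(is(snapshot, "Snapshot"), is(truth, "GroundTruth"))
    ids <- snapshot@cellIds
    arms <- setdiff(unique(truth@arm[!is.na(truth@arm)]), "trunk")
    early <- ids[!truth@outlier & !is.na(truth@s) & truth@s < earlyCutoff]
    latePool <- lapply(arms, function(a)
        ids[!truth@outlier & !is.na(truth@s) & truth@s > lateCutoff &
            truth@arm == a])
    names(latePool) <- arms
    if (length(early) < nClones)
        stop("not enough early cells for ", nClones, " clones")
    withSeed(seed, {
        founders <- sample(early, nClones)
        rows <- list()
        for (ci in seq_len(nClones)) {
            f <- founders[ci]
            cloneId <- sprintf("clone_%03d", ci)
            cand <- if (truth@arm[f] %in% arms) truth@arm[f] else arms
            rows[[length(rows) + 1L]] <-
                data.frame(cell_id = f, clone_id = cloneId,
                           time_label = "early",
                           fate_annotation = NA_character_,
                           stringsAsFactors = FALSE)
            for (si in seq_len(sistersPerClone)) {
                a <- if (length(cand) == 1L) cand else sample(cand, 1L)
                pool <- latePool[[a]]
                if (!length(pool))
                    stop("not enough late cells in arm '", a, "'")
                cell <- if (length(pool) == 1L) pool else sample(pool, 1L)
                latePool[[a]] <- setdiff(pool, cell)
                rows[[length(rows) + 1L]] <-
                    data.frame(cell_id = cell, clone_id = cloneId,
                               time_label = "late", fate_annotation = a,
                               stringsAsFactors = FALSE)
            }
        }
        do.call(rbind, rows)
    })
}
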