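## A converged small instance shared across the analysis tests.
.analysisFit <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            inst <- mkInstance(2, 5, 3, seed = 101, fates = c("A", "B"))
            fit <- proximalSolve(inst$costs, inst$partition,
                                 testConfig(4, 10))
            cache <<- list(inst = inst, fit = fit)
        }
        cache
    }
})

test_that("stage distributions are hand-recoverable plan sums", {
    x <- .analysisFit()
    part <- x$inst$partition
    plans <- x$fit$plans
    D <- stageDistributions(plans, part)
    expect_equal(rowSums(D), rep(1, nrow(D)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    ## initial cells are point masses at stage 0
    expect_equal(unname(D[initialStates(part), 1]), rep(1, 2))
    expect_equal(unname(rowSums(D[initialStates(part), -1, drop = FALSE])),
                 rep(0, 2))
    ## intermediate rows equal manually summed outgoing plan rows
    i <- 3L  # third intermediate cell
    manual <- c(0,
                rowSums(plans@Mtilde[[2]])[i] + rowSums(plans@Mhat[[2]])[i],
                rowSums(plans@Mtilde[[3]])[i] + rowSums(plans@Mhat[[3]])[i],
                rowSums(plans@Mhat[[4]])[i])
    expect_equal(unname(D[intermediateStates(part)[i], ]),
                 unname(manual / sum(manual)), tolerance = 1e-12)
    ## terminal rows equal incoming column sums
    j <- 2L
    manualT <- vapply(plans@Mhat, function(M) colSums(M)[j], 1)
    expect_equal(unname(D[terminalStates(part)[j], ]),
                 manualT / sum(manualT), tolerance = 1e-12)
})

test_that("pseudotime is the mean stage, shifted for terminals, min-max
           scaled", {
    ids <- paste0("c", 1:3)
    part <- statePartition(ids, "c1", "c3", "F")
    ## point mass at stage 3 has raw mean stage 3; terminals shift by +1
    D <- rbind(c(1, 0, 0, 0, 0),
               c(0, 0, 0, 1, 0),
               c(0, 0, 0, 0, 1))
    rownames(D) <- ids
    pt <- msotPseudotime(D, part)
    expect_equal(pt$raw_mean_stage, c(0, 3, 5))  # terminal: 4 + 1
    expect_equal(pt$pseudotime, c(0, 0.6, 1))
    ## raw values {0, 5, 10} map to {0, 0.5, 1}: c2 intermediate at
    ## stage 5, c3 terminal receiving at stage 9 (raw 9 + 1)
    D2 <- rbind(c(1, rep(0, 10)),
                c(rep(0, 5), 1, rep(0, 5)),
                c(rep(0, 9), 1, 0))
    rownames(D2) <- ids
    part2 <- statePartition(ids, "c1", "c3", "F")
    pt2 <- msotPseudotime(D2, part2)
    expect_equal(pt2$raw_mean_stage, c(0, 5, 10))
    expect_equal(pt2$pseudotime, c(0, 0.5, 1))
    ## a constant distribution maps to 0 by convention
    part3 <- statePartition(ids, "c1", "c2", "F")
    D3 <- matrix(rep(c(1, 0), each = 3), 3,
                 dimnames = list(ids, NULL))
    expect_equal(msotPseudotime(D3, part3)$pseudotime[c(1, 3)], c(0, 0))
})

test_that("pseudotime on a noiseless single-arm skeleton recovers the
           skeleton order exactly", {
    spec <- skeletonSpec(armDirections = rbind(c(0, 1)),
                         armNames = "tip", nCells = 40, noiseSd = 0,
                         nInitial = 2, nTerminalPerArm = 2, seed = 3)
    sim <- makeBranchingSnapshot(spec)
    costs <- normalizeCosts(computeCosts(sim$snapshot, sim$partition))
    fit <- proximalSolve(costs, sim$partition, testConfig(5, 10))
    pt <- msotPseudotime(stageDistributions(fit$plans, sim$partition),
                         sim$partition)
    ## designated initial/terminal cells are pinned to the end stages (tied
    ## pseudotime by construction); among free cells the order is exact
    free <- cellIds(sim$snapshot)[intermediateStates(sim$partition)]
    sel <- match(free, pt$cell_id)
    expect_equal(cor(pt$pseudotime[sel], sim$truth@s[free],
                     method = "spearman"), 1)
    ## and over all cells the ranking is still essentially perfect
    expect_gte(cor(pt$pseudotime, sim$truth@s[pt$cell_id],
                   method = "spearman"), 0.999)
})

test_that("aggregated transitions form an absorbing row-stochastic chain", {
    x <- .analysisFit()
    part <- x$inst$partition
    model <- aggregateTransitions(x$fit$plans, part)
    P <- transitionMatrix(model)
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    for (j in terminalStates(part)) {
        expect_equal(unname(P[j, j]), 1)
        expect_equal(sum(P[j, -j]), 0)
    }
    ## A equals stagewise sums recomputed independently
    A <- aggregatedMass(model)
    plans <- x$fit$plans
    i0 <- initialStates(part)[1]; xj <- intermediateStates(part)[2]
    expect_equal(A[i0, xj], plans@Mtilde[[1]][1, 2])
    manual <- plans@Mtilde[[2]][3, 2] + plans@Mtilde[[3]][3, 2]
    expect_equal(A[intermediateStates(part)[3], xj], manual)
    tsum <- plans@Mhat[[2]][3, 1] + plans@Mhat[[3]][3, 1] +
        plans@Mhat[[4]][3, 1]
    expect_equal(A[intermediateStates(part)[3], terminalStates(part)[1]],
                 tsum)

    ## plans routing one unit along a single path give indicator rows
    ids <- c("i", "x", "t")
    p3 <- statePartition(ids, "i", "t", "F")
    plans3 <- new("StagePlans",
                  Mtilde = list(matrix(1, 1, 1)),
                  Mhat = list(matrix(0, 1, 1), matrix(1, 1, 1)),
                  nStages = 2L)
    P3 <- transitionMatrix(aggregateTransitions(plans3, p3))
    expect_equal(unname(P3["i", ]), c(0, 1, 0))
    expect_equal(unname(P3["x", ]), c(0, 0, 1))
})

test_that("fate probabilities solve the absorption system", {
    ## single transient state: stay 0.5, to A 0.3, to B 0.2
    ids <- c("x", "tA", "tB")
    part <- statePartition(ids, initial = "x", terminal = c("tA", "tB"),
                           fateOf = c("A", "B"))
    P <- rbind(c(0.5, 0.3, 0.2), c(0, 1, 0), c(0, 0, 1))
    dimnames(P) <- list(ids, ids)
    model <- new("TransitionModel", P = P, A = P, cellIds = ids,
                 terminal = 2:3)
    Fm <- fateProbabilities(model, part)
    expect_equal(unname(Fm["x", ]), c(0.6, 0.4))  # 0.3 / 0.5, 0.2 / 0.5
    expect_equal(unname(Fm["tA", ]), c(1, 0))

    ## a cell whose only transition is to a class-A terminal
    P2 <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 0, 1))
    dimnames(P2) <- list(ids, ids)
    m2 <- new("TransitionModel", P = P2, A = P2, cellIds = ids,
              terminal = 2:3)
    expect_equal(unname(fateProbabilities(m2, part)["x", ]), c(1, 0))

    ## unreachable terminals are reported with the offending cell
    P3 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    dimnames(P3) <- list(ids, ids)
    m3 <- new("TransitionModel", P = P3, A = P3, cellIds = ids,
              terminal = 2:3)
    expect_error(fateProbabilities(m3, part), "x")
})

test_that("fate probabilities agree with a Monte-Carlo walk oracle", {
    ## random absorbing chain over 15 cells (10 transient, 5 terminal)
    set.seed(55)
    ids <- paste0("c", 1:15)
    part <- statePartition(ids, initial = ids[1:2], terminal = ids[11:15],
                           fateOf = c("A", "A", "B", "B", "C"))
    P <- matrix(0, 15, 15, dimnames = list(ids, ids))
    for (i in 1:10) {
        w <- runif(15) * (runif(15) < 0.4)
        w[11:15] <- w[11:15] * 0.5
        if (sum(w) == 0) w[sample(11:15, 1)] <- 1
        P[i, ] <- w / sum(w)
    }
    P[cbind(11:15, 11:15)] <- 1
    model <- new("TransitionModel", P = P, A = P, cellIds = ids,
                 terminal = 11:15)
    Fm <- fateProbabilities(model, part)
    expect_equal(rowSums(Fm), rep(1, 15), tolerance = 1e-8,
                 ignore_attr = TRUE)

    nWalk <- 10000L
    classOf <- setNames(fateOf(part), ids[terminalStates(part)])
    classes <- fateClasses(part)
    for (i in c(1, 4, 8)) {
        counts <- setNames(numeric(length(classes)), classes)
        for (r in seq_len(nWalk)) {
            st <- i
            while (st <= 10) st <- sample.int(15, 1, prob = P[st, ])
            cl <- classOf[ids[st]]
            counts[cl] <- counts[cl] + 1
        }
        phat <- counts / nWalk
        se <- sqrt(pmax(phat * (1 - phat), 1e-6) / nWalk)
        expect_true(all(abs(phat - Fm[i, classes]) <= 3 * se + 1e-3))
    }
})

test_that("fate entropy is Shannon entropy with configurable base", {
    ids <- c("a", "b", "t")
    part <- statePartition(ids, "a", "t", "A")
    Fm <- rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25), c(1, 0, 0, 0))
    rownames(Fm) <- ids
    H <- fateEntropy(Fm, part)
    expect_equal(unname(H$perCell), c(0, log(4), 0))
    expect_equal(H$meanNonTerminal, mean(c(0, log(4))))
    H2 <- fateEntropy(Fm, part, base = 2)
    expect_equal(unname(H2$perCell[2]), 2)
})

test_that("outlier flags use a strict threshold on the unknown fate", {
    Fm <- rbind(c(0.49, 0.51), c(0.51, 0.49), c(0.5, 0.5))
    dimnames(Fm) <- list(c("a", "b", "c"), c("A", "unknown"))
    fl <- flagOutliers(Fm, 0.5)
    expect_equal(unname(fl), c(TRUE, FALSE, FALSE))  # 0.5 itself not above
    noUnknown <- Fm[, 1, drop = FALSE]
    expect_error(flagOutliers(noUnknown), "unknown")
})

test_that("fate gating applies strict two-sided thresholds", {
    Fm <- rbind(c(0.5, 0.5, 0, 0),
                c(0.05, 0.9, 0.03, 0.02),
                c(0.2, 0.2, 0.005, 0.005))
    dimnames(Fm) <- list(c("a", "b", "c"), c("Ma", "Ba", "Ery", "Neu"))
    got <- gateCells(Fm, c("Ma", "Ba"))
    expect_setequal(got, c("a", "c"))  # b fails: Ma below 10%
    expect_error(gateCells(Fm, "Nope"), "unknown fate class")
})
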