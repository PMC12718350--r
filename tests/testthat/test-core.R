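test_that("preprocessCounts applies median size-factor scaling then log1p", {
    ## zero stays zero, and equal totals reduce to plain log1p
    m <- rbind(c(0, 2, 8), c(4, 6, 0))  # equal totals (10)
    sn <- preprocessCounts(Snapshot(m))
    expect_equal(unname(stateMatrix(sn)), log1p(m))
    expect_equal(unname(stateMatrix(sn)[1, 1]), 0)

    ## 3 x 2 toy against an independent hand computation:
    ## totals 3, 30, 12; median total 12; size factors 1/4, 5/2, 1
    toy <- rbind(c(1, 2), c(10, 20), c(4, 8))
    expected <- log1p(toy / (c(3, 30, 12) / 12))
    expect_equal(unname(stateMatrix(preprocessCounts(Snapshot(toy)))),
                 expected)

    expect_error(preprocessCounts(Snapshot(matrix(0, 2, 2))), "zero total")
    emb <- Snapshot(matrix(1, 2, 2), isEmbedding = TRUE)
    expect_error(preprocessCounts(emb), "embedding")
})

test_that("pcaEmbed preserves geometry and orders variance", {
    set.seed(11)
    ## full-rank case: a rigid transform preserves pairwise distances
    m <- matrix(runif(40), ncol = 2)
    sn <- Snapshot(m, isEmbedding = FALSE)
    emb <- pcaEmbed(sn, nComponents = 2)
    expect_equal(as.matrix(dist(stateMatrix(emb))), as.matrix(dist(m)),
                 tolerance = 1e-12, ignore_attr = TRUE)

    ## explained variance non-increasing and equal to covariance eigenvalues
    m2 <- matrix(runif(100), 20, 5)
    emb2 <- pcaEmbed(Snapshot(m2), nComponents = 5)
    ev <- attr(stateMatrix(emb2), "explainedVariance")
    expect_false(is.unsorted(rev(ev)))
    expect_equal(ev, sort(eigen(cov(m2))$values, decreasing = TRUE),
                 tolerance = 1e-10)
    ## retained variance cannot exceed total input variance
    emb3 <- pcaEmbed(Snapshot(m2), nComponents = 3)
    expect_lte(sum(attr(stateMatrix(emb3), "explainedVariance")),
               sum(diag(cov(m2))) + 1e-12)

    expect_error(pcaEmbed(Snapshot(m2), nComponents = 6), "nComponents")
})

test_that("computeCosts matches a brute-force double loop", {
    ids <- paste0("c", 1:6)
    set.seed(3)
    co <- matrix(runif(12), ncol = 2, dimnames = list(ids, NULL))
    sn <- Snapshot(co, isEmbedding = TRUE)
    part <- statePartition(ids, initial = "c1", terminal = c("c5", "c6"),
                           fateOf = c("A", "B"))
    cs <- computeCosts(sn, part)
    brute <- function(i, j) sum((co[i, ] - co[j, ])^2)
    X <- intermediateStates(part)
    for (a in seq_along(initialStates(part)))
        for (b in seq_along(X))
            expect_equal(costMatrix(cs, "C0X")[a, b],
                         brute(initialStates(part)[a], X[b]))
    for (a in seq_along(X))
        for (b in seq_along(X))
            expect_equal(costMatrix(cs, "CXX")[a, b], brute(X[a], X[b]),
                         tolerance = 1e-12)
    expect_equal(unname(diag(costMatrix(cs, "CXX"))), rep(0, 3))
    expect_equal(costMatrix(cs, "CXX"), t(costMatrix(cs, "CXX")))

    ## the worked point pair (0,0) -> (1,1) has cost 2
    sn2 <- Snapshot(rbind(c(0, 0), c(0.5, 0), c(1, 1)),
                    cellIds = c("i", "x", "t"), isEmbedding = TRUE)
    p2 <- statePartition(c("i", "x", "t"), "i", "t", "F")
    expect_equal(computeCosts(sn2, p2)@C0F[1, 1], 2)
})

test_that("normalizeCosts divides by the pooled median and is idempotent", {
    ## pooled entries {1,2,3}: n = 0 so the pool is C0F alone
    cs <- new("CostSet", C0X = matrix(0, 1, 0), C0F = matrix(c(1, 2, 3), 1),
              CXX = matrix(0, 0, 0), CXF = matrix(0, 0, 3),
              normalizationFactor = 1, auxCostQ = NA_real_)
    nm <- normalizeCosts(cs)
    expect_equal(as.vector(nm@C0F), c(0.5, 1, 1.5))
    expect_equal(normalizationFactor(nm), 2)
    again <- normalizeCosts(nm)
    expect_equal(again@C0F, nm@C0F, tolerance = 1e-12)

    ## random cost set: pooled median of the output is 1; rescaling the
    ## coordinates by s multiplies the factor by s^2 and leaves the
    ## normalized costs unchanged
    inst <- mkInstance(2, 5, 3, seed = 21)
    pooled <- c(inst$costs@C0X, inst$costs@C0F, inst$costs@CXX,
                inst$costs@CXF)
    expect_equal(median(pooled), 1, tolerance = 1e-9)
    s <- 3.7
    sc <- Snapshot(stateMatrix(inst$snapshot) * s,
                   cellIds = cellIds(inst$snapshot), isEmbedding = TRUE)
    cs2 <- normalizeCosts(computeCosts(sc, inst$partition))
    expect_equal(cs2@CXX, inst$costs@CXX, tolerance = 1e-9)
    expect_equal(normalizationFactor(cs2),
                 normalizationFactor(inst$costs) * s^2, tolerance = 1e-9)

    zero <- new("CostSet", C0X = matrix(0, 1, 1), C0F = matrix(0, 1, 1),
                CXX = matrix(0, 1, 1), CXF = matrix(0, 1, 1),
                normalizationFactor = 1, auxCostQ = NA_real_)
    expect_error(normalizeCosts(zero), "degenerate")
})

test_that("partitionSubsets deals equal stratified shares deterministically", {
    sim <- makeBranchingSnapshot(skeletonSpec(nCells = 97, seed = 5))
    ## k = 1 is the identity partition
    one <- partitionSubsets(sim$snapshot, sim$partition, 1, seed = 1)
    expect_length(one, 1L)
    expect_equal(cellIds(one[[1]]$snapshot), cellIds(sim$snapshot))

    for (k in c(2, 3, 5)) {
        subs <- partitionSubsets(sim$snapshot, sim$partition, k, seed = k)
        allIds <- unlist(lapply(subs, function(s) cellIds(s$snapshot)))
        expect_false(anyDuplicated(allIds) > 0)           # disjoint
        expect_setequal(allIds, cellIds(sim$snapshot))     # coverage
        n0s <- vapply(subs, function(s) nInitial(s$partition), 1L)
        expect_lte(diff(range(n0s)), 1L)
        for (cl in fateClasses(sim$partition)) {
            nfs <- vapply(subs, function(s)
                sum(fateOf(s$partition) == cl), 1L)
            expect_lte(diff(range(nfs)), 1L)
        }
    }
    a <- partitionSubsets(sim$snapshot, sim$partition, 3, seed = 9)
    b <- partitionSubsets(sim$snapshot, sim$partition, 3, seed = 9)
    expect_identical(lapply(a, function(s) cellIds(s$snapshot)),
                     lapply(b, function(s) cellIds(s$snapshot)))

    expect_error(partitionSubsets(sim$snapshot, sim$partition, 6),
                 "fewer")
})

test_that("a 12-way split of a 120/6972 design gives 10 + 581 per subset", {
    n0 <- 120L; nF <- 6972L; nX <- 108L
    N <- n0 + nF + nX
    ids <- paste0("c", seq_len(N))
    sn <- Snapshot(matrix(seq_len(N), ncol = 1), cellIds = ids,
                   isEmbedding = TRUE)
    part <- statePartition(ids, initial = ids[seq_len(n0)],
                           terminal = ids[(n0 + nX + 1):N],
                           fateOf = rep("F", nF))
    subs <- partitionSubsets(sn, part, 12, seed = 0)
    expect_equal(vapply(subs, function(s) nInitial(s$partition), 1L),
                 rep(10L, 12))
    expect_equal(vapply(subs, function(s) nTerminal(s$partition), 1L),
                 rep(581L, 12))
})

test_that("augmentAuxiliary appends one state per tier at fixed cost Q", {
    inst <- mkInstance(2, 4, 3, seed = 31)
    n <- nIntermediate(inst$partition)
    aug <- augmentAuxiliary(inst$costs, inst$partition, Q = 3.25)
    expect_true(auxEnabled(aug$partition))
    expect_equal(auxCostQ(aug$costs), 3.25)
    CXX <- costMatrix(aug$costs, "CXX")
    expect_equal(dim(CXX), c(n + 1L, n + 1L))
    expect_equal(CXX[n + 1L, seq_len(n)], rep(3.25, n))
    expect_equal(CXX[seq_len(n), n + 1L], rep(3.25, n))
    expect_equal(CXX[n + 1L, n + 1L], 0)
    expect_equal(costMatrix(aug$costs, "C0F")[3, 4], 0)  # aux-to-aux free
    expect_true("unknown" %in% fateClasses(aug$partition))
    expect_equal(fateOf(aug$partition)[nTerminal(aug$partition)], "unknown")
    ## an alternative Q is accepted; nonpositive Q is not
    expect_silent(augmentAuxiliary(inst$costs, inst$partition, Q = 2))
    expect_error(augmentAuxiliary(inst$costs, inst$partition, Q = 0),
                 "Q must be > 0")
})
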