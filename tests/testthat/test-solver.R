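test_that("sinkhornBimarginal solves trivial and near-LP instances", {
    ## 1 x 1: the single route carries all mass whatever the cost
    M <- sinkhornBimarginal(matrix(4.2, 1, 1), 1, 1, epsilon = 0.5)
    expect_equal(M[1, 1], 1, tolerance = 1e-9)

    ## 2 x 2 crossing costs at small epsilon: half the mass down each
    ## diagonal entry (LP optimum 0.5 * I, objective 0)
    C <- matrix(c(0, 1, 1, 0), 2)
    M <- sinkhornBimarginal(C, c(0.5, 0.5), c(0.5, 0.5), epsilon = 1e-3)
    expect_equal(M, 0.5 * diag(2), tolerance = 1e-6, ignore_attr = TRUE)
    expect_lt(sum(C * M), 1e-6)

    ## symmetric cost and marginals give a symmetric plan
    set.seed(4)
    S <- matrix(runif(9), 3); S <- S + t(S)
    M <- sinkhornBimarginal(S, rep(1, 3), rep(1, 3), epsilon = 0.1)
    expect_equal(M, t(M), tolerance = 1e-8, ignore_attr = TRUE)

    expect_error(sinkhornBimarginal(C, c(1, 1), c(0.5, 0.5), 0.1),
                 "unbalanced")
})

test_that("sinkhornBimarginal meets equality and lower-bound marginals", {
    set.seed(8)
    for (rep in 1:5) {
        C <- matrix(runif(12), 3, 4)
        mu1 <- runif(3, 0.5, 2); mu2 <- runif(4, 0.5, 2)
        mu2 <- mu2 * sum(mu1) / sum(mu2)
        M <- sinkhornBimarginal(C, mu1, mu2, epsilon = 0.05, tau = 1e-8)
        expect_equal(rowSums(M), mu1, tolerance = 1e-6, ignore_attr = TRUE)
        expect_equal(colSums(M), mu2, tolerance = 1e-6, ignore_attr = TRUE)
        ## lower-bound mode: marginals become elementwise floors
        L <- sinkhornBimarginal(C, mu1, mu2, epsilon = 0.05, tau = 1e-8,
                                mode = "lower")
        expect_true(all(rowSums(L) >= mu1 - 1e-6))
        expect_true(all(colSums(L) >= mu2 - 1e-6))
    }
    ## log-domain agrees with the plain domain
    C <- matrix(runif(6), 2, 3)
    mu1 <- c(1, 2); mu2 <- c(1, 1, 1)
    M1 <- sinkhornBimarginal(C, mu1, mu2, epsilon = 0.05, tau = 1e-9)
    M2 <- sinkhornBimarginal(C, mu1, mu2, epsilon = 0.05, tau = 1e-9,
                             logDomain = TRUE)
    expect_equal(M1, M2, tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("with no intermediates the solve is one bimarginal transport", {
    ## n0 = nF = 1, cost c: exactly one unit moves (extra mass only costs)
    ids <- c("i", "t")
    sn <- Snapshot(matrix(c(0, 2), ncol = 1), cellIds = ids,
                   isEmbedding = TRUE)
    part <- statePartition(ids, "i", "t", "F")
    cs <- computeCosts(sn, part)
    fit <- solveMsotEntropic(cs, part, msotConfig(nStages = 2,
                                                  epsilonStart = 0.01))
    expect_equal(fit$plans@Mhat[[1]][1, 1], 1, tolerance = 1e-4)
    expect_equal(transportCost(fit$report), 4, tolerance = 1e-3)

    ## plans equal the inequality-marginal bimarginal solution
    ids <- c("i1", "i2", "t1", "t2", "t3")
    set.seed(13)
    sn <- Snapshot(matrix(runif(10), ncol = 2), cellIds = ids,
                   isEmbedding = TRUE)
    part <- statePartition(ids, initial = c("i1", "i2"),
                           terminal = c("t1", "t2", "t3"),
                           fateOf = c("A", "A", "B"))
    cs <- computeCosts(sn, part)
    fit <- solveMsotEntropic(cs, part, msotConfig(nStages = 2,
                                                  epsilonStart = 0.1,
                                                  tol = 1e-9))
    direct <- sinkhornBimarginal(cs@C0F, rep(1, 2), rep(1, 3),
                                 epsilon = 0.1, tau = 1e-9,
                                 mode = "lower")
    expect_equal(fit$plans@Mhat[[1]], direct, tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("the 3-cell chain routes through the midpoint at half the cost", {
    ch <- mkChain()
    cfg <- testConfig(3, proxIters = 25)
    fit <- proximalSolve(ch$costs, ch$partition, cfg)
    expect_true(converged(fit$report))
    ## LP optimum (frozen from the flow-polytope oracle): 0.25 + 0.25
    expect_equal(transportCost(fit$report), 0.5, tolerance = 1e-3)
    expect_lt(transportCost(fit$report), 1.0)  # beats the direct route
    expect_lte(constraintResiduals(fit$plans, ch$partition)$max, 1e-4)

    ## the proximal path approximates a direct small-epsilon solve
    direct <- solveMsotEntropic(ch$costs, ch$partition,
                                msotConfig(nStages = 3,
                                           epsilonStart = 0.002,
                                           logDomain = TRUE))
    expect_equal(transportCost(fit$report),
                 transportCost(direct$report), tolerance = 1e-2)
})

test_that("a random instance matches the LP oracle", {
    inst <- mkInstance(2, 4, 3, seed = 42)
    lp <- msotLP(inst$costs, inst$partition, 4)
    fit <- proximalSolve(inst$costs, inst$partition, testConfig(4))
    expect_true(converged(fit$report))
    expect_equal(transportCost(fit$report), lp$fun,
                 tolerance = 1e-3)
})

test_that("proximal rounds anneal the regularization monotonically", {
    inst <- mkInstance(2, 3, 2, seed = 17)
    cfg <- msotConfig(nStages = 4, epsilonStart = 0.05, proxIters = 1)
    ## prox_iters = 1 is exactly one entropic solve
    a <- proximalSolve(inst$costs, inst$partition, cfg)
    b <- solveMsotEntropic(inst$costs, inst$partition, cfg)
    expect_identical(a$plans@Mhat, b$plans@Mhat)
    expect_identical(a$plans@Mtilde, b$plans@Mtilde)

    ## transport cost is non-increasing over the proximal rounds
    prior <- NULL
    costs <- c()
    for (k in 1:6) {
        r <- solveMsotEntropic(inst$costs, inst$partition, cfg,
                               prior = prior)
        costs <- c(costs, transportCost(r$report))
        prior <- r$plans
    }
    expect_true(all(diff(costs) <= 1e-8))
})

test_that("the solver is deterministic", {
    inst <- mkInstance(2, 4, 2, seed = 5)
    f1 <- proximalSolve(inst$costs, inst$partition, testConfig(4, 5))
    f2 <- proximalSolve(inst$costs, inst$partition, testConfig(4, 5))
    expect_identical(f1$plans@Mtilde, f2$plans@Mtilde)
    expect_identical(f1$plans@Mhat, f2$plans@Mhat)
})

test_that("log-domain and plain updates agree", {
    inst <- mkInstance(2, 3, 2, seed = 23)
    p <- solveMsotEntropic(inst$costs, inst$partition,
                           msotConfig(nStages = 4, epsilonStart = 0.05))
    l <- solveMsotEntropic(inst$costs, inst$partition,
                           msotConfig(nStages = 4, epsilonStart = 0.05,
                                      logDomain = TRUE))
    expect_equal(p$plans@Mhat, l$plans@Mhat, tolerance = 1e-6)
    expect_equal(transportCost(p$report), transportCost(l$report),
                 tolerance = 1e-6)
})

test_that("extreme distances without auxiliary states raise an instability
           error that names the cells", {
    ids <- c("i", "x1", "far", "t")
    co <- rbind(c(0, 0), c(0.4, 0), c(50, 50), c(1, 0))
    sn <- Snapshot(co, cellIds = ids, isEmbedding = TRUE)
    part <- statePartition(ids, "i", "t", "F")
    cs <- computeCosts(sn, part)
    expect_error(
        solveMsotEntropic(cs, part, msotConfig(nStages = 3,
                                               epsilonStart = 0.05)),
        "far")
})

test_that("constraintResiduals measures coupling and lower-bound violations", {
    inst <- mkInstance(2, 4, 3, seed = 77)
    Tn <- 4L
    ## forward-simulated feasible flows couple exactly
    plans <- mkFeasiblePlans(inst$partition, Tn, seed = 1)
    r <- constraintResiduals(plans, inst$partition)
    expect_lt(r$coupling, 1e-12)
    expect_equal(r$initial, 0)

    ## intermediate cells exiting only half of what they received in the
    ## final stage: the coupling residual is exactly that shortfall
    plans2 <- plans
    inc <- colSums(plans2@Mtilde[[3]])
    plans2@Mhat[[4]] <- plans2@Mhat[[4]] * 0
    plans2@Mhat[[4]][, 1] <- inc * 0.5
    expect_equal(constraintResiduals(plans2, inst$partition)$coupling,
                 max(inc * 0.5), tolerance = 1e-12)

    ## converged solver output satisfies everything at tolerance, and the
    ## exiting mass covers max(n0, nF) up to tau slack
    fit <- proximalSolve(inst$costs, inst$partition, testConfig(Tn, 5))
    rr <- constraintResiduals(fit$plans, inst$partition)
    expect_lte(rr$max, 1e-4)
    exiting <- sum(vapply(fit$plans@Mhat, sum, 1))
    n0 <- nInitial(inst$partition); nF <- nTerminal(inst$partition)
    expect_gte(exiting, max(n0, nF) - 1e-4 * (n0 + nF))
    ## stage coupling conserves mass: everything emitted eventually exits
    expect_equal(exiting, sum(fit$plans@Mtilde[[1]]) +
                              sum(fit$plans@Mhat[[1]]),
                 tolerance = 1e-3)
})
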