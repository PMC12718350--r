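## Fixture builders (all generated in code; no stored data).

## Random 2D instance with n0 initial, n intermediate, nF terminal cells.
mkInstance <- function(n0, n, nF, seed, fates = c("A", "B")) {
    set.seed(seed)
    N <- n0 + n + nF
    ids <- paste0("c", seq_len(N))
    sn <- Snapshot(matrix(runif(2 * N), ncol = 2), cellIds = ids,
                   isEmbedding = TRUE)
    fateOf <- rep(fates, length.out = nF)
    part <- statePartition(ids, initial = ids[seq_len(n0)],
                           terminal = ids[(n0 + n + 1):N],
                           fateOf = fateOf,
                           fateClasses = intersect(fates, fateOf))
    list(snapshot = sn, partition = part,
         costs = normalizeCosts(computeCosts(sn, part)))
}

## The 3-cell chain 0 -> 0.5 -> 1.0 (one initial, one intermediate, one
## terminal), unnormalized squared-Euclidean costs.
mkChain <- function() {
    ids <- c("a", "b", "c")
    sn <- Snapshot(matrix(c(0, 0.5, 1.0), ncol = 1), cellIds = ids,
                   isEmbedding = TRUE)
    part <- statePartition(ids, initial = "a", terminal = "c", fateOf = "F")
    list(snapshot = sn, partition = part,
         costs = computeCosts(sn, part))
}

## Feasible stage plans built by forward simulation: every initial cell
## emits >= 1 unit and the stage-coupling equalities hold by construction.
mkFeasiblePlans <- function(part, Tn, seed) {
    set.seed(seed)
    n0 <- length(part@X0); n <- length(part@X); nF <- length(part@XF)
    rdist <- function(k) { p <- runif(k) + 0.05; p / sum(p) }
    Mtilde <- list(); Mhat <- list()
    m0 <- 1 + runif(n0)
    exitFrac <- runif(n0, 0.05, 0.5)
    Mhat[[1]] <- (m0 * exitFrac) * t(vapply(seq_len(n0),
                                            function(i) rdist(nF),
                                            numeric(nF)))
    Mtilde[[1]] <- (m0 * (1 - exitFrac)) *
        t(vapply(seq_len(n0), function(i) rdist(n), numeric(n)))
    for (s in seq(2, Tn)) {
        inc <- colSums(Mtilde[[s - 1]])
        if (s < Tn) {
            ef <- runif(n, 0.05, 0.5)
            Mhat[[s]] <- (inc * ef) * t(vapply(seq_len(n),
                                               function(i) rdist(nF),
                                               numeric(nF)))
            Mtilde[[s]] <- (inc * (1 - ef)) *
                t(vapply(seq_len(n), function(i) rdist(n), numeric(n)))
        } else {
            Mhat[[s]] <- inc * t(vapply(seq_len(n),
                                        function(i) rdist(nF),
                                        numeric(nF)))
        }
    }
    new("StagePlans", Mtilde = Mtilde, Mhat = Mhat, nStages = Tn)
}

## Standard solver settings used across tests: effective epsilon 2.5e-3.
testConfig <- function(Tn, proxIters = 20L, eps = 0.05, ...) {
    msotConfig(nStages = Tn, epsilonStart = eps, proxIters = proxIters, ...)
}
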