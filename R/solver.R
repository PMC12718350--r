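## Multistage entropic transport solver.
##
## The program: over plans Mtilde[t] (mass continuing in the system at stage
## t) and Mhat[t] (mass exiting to the terminal tier at stage t), minimize
##
##   sum_{t=0}^{T-2} <Ctilde_t, Mtilde_t> + sum_{t=0}^{T-1} <Chat_t, Mhat_t>
##     + eps * sum m (log(m / prior) - 1)
##
## subject to, with muTilde/muHat/nuHat the derived row/column sums,
##   (i)   muTilde_0 + muHat_0 >= 1          per initial cell,
##   (ii)  colSums(Mtilde_{t-1}) = muTilde_t + muHat_t,  t = 1..T-1
##         (muTilde_{T-1} fixed to zero: all mass reaching the last stage
##          must exit to the terminal tier),
##   (iii) sum_t muTilde_t + sum_t muHat_t >= 1  per intermediate cell,
##   (iv)  sum_t nuHat_t >= 1                per terminal cell.
##
## Dual block coordinate ascent in scaling form: the equality duals are free
## (scaling vectors w_t > 0), the three inequality blocks carry nonnegative
## duals, i.e. scaling factors clipped at 1 (u = max(1, 1/(K v)) pattern).
## One sweep updates, in order: the stage-0 inequality block, the coupling
## equalities t = 1..T-1, the throughput inequality, the terminal
## inequality.  Convergence: maximum over dual-variable updates and absolute
## constraint deviations below the tolerance.

#' Entropic bimarginal optimal transport (Sinkhorn scaling)
#'
#' Solves `min <C, M> + epsilon * sum m (log m - 1)` over nonnegative plans
#' with prescribed row and column sums (`mode = "equality"`), or with the
#' marginals treated as elementwise lower bounds (`mode = "lower"`, the
#' one-sided variant the multistage model reduces to when there are no
#' intermediate cells).
#'
#' @param C numeric cost matrix.
#' @param mu1,mu2 source and target masses (equal totals in equality mode).
#' @param epsilon entropic regularization, `> 0`.
#' @param tau convergence tolerance on marginal deviations and dual updates.
#' @param maxIters iteration cap.
#' @param mode `"equality"` or `"lower"`.
#' @param logDomain use log-domain stabilized updates.
#' @return The optimal plan matrix, with attributes `"iterations"` and
#'   `"residual"`.
#' @examples
#' sinkhornBimarginal(matrix(c(0, 1, 1, 0), 2), c(.5, .5), c(.5, .5), 0.01)
#' @export
sinkhornBimarginal <- function(C, mu1, mu2, epsilon, tau = 1e-9,
                               maxIters = 100000L,
                               mode = c("equality", "lower"),
                               logDomain = FALSE) {
    mode <- match.arg(mode)
    C <- as.matrix(C)
    stopifnot(length(mu1) == nrow(C), length(mu2) == ncol(C))
    if (epsilon <= 0) stop("epsilon must be > 0")
    if (any(mu1 < 0) || any(mu2 < 0)) stop("marginals must be >= 0")
    if (mode == "equality" &&
        abs(sum(mu1) - sum(mu2)) > 1e-8 * max(1, sum(mu1)))
        stop("unbalanced masses: sum(mu1) must equal sum(mu2)")
    if (sum(mu1) == 0) stop("total mass must be positive")

    if (logDomain) {
        lK <- -C / epsilon
        lu <- numeric(nrow(C)); lv <- numeric(ncol(C))
        lmu1 <- log(mu1); lmu2 <- log(mu2)
        for (it in seq_len(maxIters)) {
            lr <- rowLogSumExp(lK, lv)
            lu2 <- if (mode == "equality") lmu1 - lr else pmax(lmu1 - lr, 0)
            lc <- colLogSumExp(lK + lu2, NULL)
            lv2 <- if (mode == "equality") lmu2 - lc else pmax(lmu2 - lc, 0)
            d <- epsilon * max(abs(lu2 - lu)[mu1 > 0],
                               abs(lv2 - lv)[mu2 > 0], 0)
            lu <- lu2; lv <- lv2
            if (d < tau) {
                rs <- exp(lu + rowLogSumExp(lK, lv))
                cs <- exp(lv + colLogSumExp(lK + lu, NULL))
                dev <- if (mode == "equality")
                           max(abs(rs - mu1), abs(cs - mu2))
                       else max(pmax(mu1 - rs, 0), pmax(mu2 - cs, 0))
                if (dev < tau) {
                    M <- exp(lK + outer(lu, lv, "+"))
                    attr(M, "iterations") <- it
                    attr(M, "residual") <- max(d, dev)
                    return(M)
                }
            }
        }
        stop("Sinkhorn did not converge within maxIters")
    }

    K <- exp(-C / epsilon)
    if (any(rowSums(K) == 0) || any(colSums(K) == 0))
        stop("kernel underflow: exp(-C/epsilon) has an all-zero row or ",
             "column; increase epsilon, enable logDomain, or use auxiliary ",
             "states")
    u <- rep(1, nrow(C)); v <- rep(1, ncol(C))
    for (it in seq_len(maxIters)) {
        Kv <- drop(K %*% v)
        u2 <- if (mode == "equality") mu1 / Kv else pmax(mu1 / Kv, 1)
        Ku <- drop(crossprod(K, u2))
        v2 <- if (mode == "equality") mu2 / Ku else pmax(mu2 / Ku, 1)
        if (!all(is.finite(u2[mu1 > 0])) || !all(is.finite(v2[mu2 > 0])))
            stop("numerical instability in Sinkhorn scaling; increase ",
                 "epsilon or enable logDomain")
        d <- epsilon * max(abs(log(u2 / u))[mu1 > 0],
                           abs(log(v2 / v))[mu2 > 0], 0)
        u <- u2; v <- v2
        if (d < tau) {
            rs <- u * drop(K %*% v)
            cs <- v * drop(crossprod(K, u))
            dev <- if (mode == "equality") max(abs(rs - mu1), abs(cs - mu2))
                   else max(pmax(mu1 - rs, 0), pmax(mu2 - cs, 0))
            if (dev < tau) {
                M <- K * outer(u, v)
                attr(M, "iterations") <- it
                attr(M, "residual") <- max(d, dev)
                return(M)
            }
        }
    }
    stop("Sinkhorn did not converge within maxIters")
}

## Internal: generalized Sinkhorn sweeps on prepared kernels (plain domain).
## Kt: list of continuing kernels (first n0 x n, then n x n), length T-1.
## Kh: list of exiting kernels (first n0 x nF, then n x nF), length T.
## Returns scalings, iterations and final residual.
.msotScale <- function(Kt, Kh, eps, tol, maxIters, labels) {
    Tn <- length(Kh)
    S1 <- length(Kt)
    n0 <- nrow(Kh[[1L]]); nF <- ncol(Kh[[1L]])
    n <- if (S1 > 0L) ncol(Kt[[1L]]) else 0L
    a <- rep(1, n0); g <- rep(1, nF)
    b <- rep(1, n)
    w <- rep(list(rep(1, n)), S1)

    fail <- function(mask, who) {
        stop("numerical instability (kernel underflow) for ", who,
             " cells: ",
             paste(utils::head(labels[[who]][mask], 5L), collapse = ", "),
             "; increase epsilon, enable logDomain, or add auxiliary states")
    }
    outSum <- function(s) {
        o <- drop(Kh[[s + 1L]] %*% g)
        if (s < S1) o <- o + drop(Kt[[s + 1L]] %*% w[[s + 1L]])
        o
    }
    inSum <- function(s) {
        drop(crossprod(Kt[[s]], if (s == 1L) a else b / w[[s - 1L]]))
    }

    for (it in seq_len(maxIters)) {
        dmax <- 0
        ## stage-0 inequality
        s0 <- if (S1 > 0L) drop(Kt[[1L]] %*% w[[1L]]) + drop(Kh[[1L]] %*% g)
              else drop(Kh[[1L]] %*% g)
        if (any(bad <- !is.finite(s0) | s0 <= 0)) fail(bad, "initial")
        a2 <- pmax(1, 1 / s0)
        dmax <- max(dmax, abs(log(a2 / a)))
        a <- a2
        ## coupling equalities t = 1..T-1
        for (s in seq_len(S1)) {
            I <- inSum(s); O <- outSum(s)
            if (any(bad <- !is.finite(I) | !is.finite(O)))
                fail(bad, "intermediate")
            ## a cell with no incoming and no outgoing kernel support at
            ## this stage is inactive here: its coupling dual is arbitrary
            inactive <- I == 0 & O == 0
            if (any(bad <- xor(I == 0, O == 0)))
                fail(bad, "intermediate")
            w2 <- w[[s]]
            w2[!inactive] <- sqrt(b[!inactive] * O[!inactive] /
                                      I[!inactive])
            dmax <- max(dmax, abs(log(w2 / w[[s]])))
            w[[s]] <- w2
        }
        ## throughput inequality
        if (S1 > 0L) {
            S <- 0
            for (s in seq_len(S1)) S <- S + outSum(s) / w[[s]]
            if (any(bad <- !is.finite(S) | S <= 0))
                fail(bad, "intermediate")
            b2 <- pmax(1, 1 / S)
            dmax <- max(dmax, abs(log(b2 / b)))
            b <- b2
        }
        ## terminal inequality
        gin <- drop(crossprod(Kh[[1L]], a))
        if (Tn >= 2L && S1 > 0L)
            for (s in 2:Tn) gin <- gin + drop(crossprod(Kh[[s]], b / w[[s - 1L]]))
        if (any(bad <- !is.finite(gin) | gin <= 0)) fail(bad, "terminal")
        g2 <- pmax(1, 1 / gin)
        dmax <- max(dmax, abs(log(g2 / g)))
        g <- g2

        dmax <- eps * dmax
        if (dmax < tol) {
            ## constraint deviations with the final scalings
            dev <- 0
            s0 <- if (S1 > 0L) drop(Kt[[1L]] %*% w[[1L]]) + drop(Kh[[1L]] %*% g)
                  else drop(Kh[[1L]] %*% g)
            dev <- max(dev, pmax(1 - a * s0, 0))
            if (S1 > 0L) {
                S <- 0
                for (s in seq_len(S1)) {
                    I <- inSum(s); O <- outSum(s)
                    dev <- max(dev, abs(w[[s]] * I - (b / w[[s]]) * O))
                    S <- S + O / w[[s]]
                }
                dev <- max(dev, pmax(1 - b * S, 0))
            }
            gin <- drop(crossprod(Kh[[1L]], a))
            if (S1 > 0L) for (s in 2:Tn)
                gin <- gin + drop(crossprod(Kh[[s]], b / w[[s - 1L]]))
            dev <- max(dev, pmax(1 - g * gin, 0))
            if (max(dmax, dev) < tol)
                return(list(a = a, b = b, w = w, g = g, iterations = it,
                            residual = max(dmax, dev), converged = TRUE))
        }
    }
    list(a = a, b = b, w = w, g = g, iterations = maxIters,
         residual = NA_real_, converged = FALSE)
}

## Internal: log-domain variant of .msotScale for small epsilon.
.msotScaleLog <- function(lKt, lKh, eps, tol, maxIters, labels) {
    Tn <- length(lKh)
    S1 <- length(lKt)
    n0 <- nrow(lKh[[1L]]); nF <- ncol(lKh[[1L]])
    n <- if (S1 > 0L) ncol(lKt[[1L]]) else 0L
    la <- numeric(n0); lg <- numeric(nF)
    lb <- numeric(n)
    lw <- rep(list(numeric(n)), S1)

    lse2 <- function(x, y) {
        m <- pmax(x, y)
        out <- m + log1p(exp(-abs(x - y)))
        out[m == -Inf] <- -Inf   # both arguments -Inf
        out
    }
    outSumL <- function(s) {
        o <- rowLogSumExp(lKh[[s + 1L]], lg)
        if (s < S1) o <- lse2(o, rowLogSumExp(lKt[[s + 1L]], lw[[s + 1L]]))
        o
    }
    inSumL <- function(s) {
        colLogSumExp(lKt[[s]], if (s == 1L) la else lb - lw[[s - 1L]])
    }

    for (it in seq_len(maxIters)) {
        dmax <- 0
        ls0 <- if (S1 > 0L) lse2(rowLogSumExp(lKt[[1L]], lw[[1L]]),
                                 rowLogSumExp(lKh[[1L]], lg))
               else rowLogSumExp(lKh[[1L]], lg)
        la2 <- pmax(0, -ls0)
        dmax <- max(dmax, abs(la2 - la)); la <- la2
        for (s in seq_len(S1)) {
            I <- inSumL(s); O <- outSumL(s)
            inactive <- I == -Inf & O == -Inf
            lw2 <- lw[[s]]
            lw2[!inactive] <- 0.5 * (lb[!inactive] + O[!inactive] -
                                         I[!inactive])
            if (!all(is.finite(lw2)))
                stop("numerical instability in log-domain updates for ",
                     "intermediate cells: ",
                     paste(utils::head(labels$intermediate[!is.finite(lw2)],
                                       5L), collapse = ", "))
            dmax <- max(dmax, abs(lw2 - lw[[s]])); lw[[s]] <- lw2
        }
        if (S1 > 0L) {
            lS <- rep(-Inf, n)
            for (s in seq_len(S1)) lS <- lse2(lS, outSumL(s) - lw[[s]])
            lb2 <- pmax(0, -lS)
            if (any(bad <- !is.finite(lb2)))
                stop("numerical instability (kernel underflow) for ",
                     "intermediate cells: ",
                     paste(utils::head(labels$intermediate[bad], 5L),
                           collapse = ", "))
            dmax <- max(dmax, abs(lb2 - lb)); lb <- lb2
        }
        lgin <- colLogSumExp(lKh[[1L]], la)
        if (S1 > 0L) for (s in 2:Tn)
            lgin <- lse2(lgin, colLogSumExp(lKh[[s]], lb - lw[[s - 1L]]))
        lg2 <- pmax(0, -lgin)
        if (any(bad <- !is.finite(lg2)))
            stop("numerical instability (kernel underflow) for terminal ",
                 "cells: ",
                 paste(utils::head(labels$terminal[bad], 5L),
                       collapse = ", "))
        dmax <- max(dmax, abs(lg2 - lg)); lg <- lg2

        dmax <- eps * dmax
        if (dmax < tol) {
            dev <- 0
            ls0 <- if (S1 > 0L) lse2(rowLogSumExp(lKt[[1L]], lw[[1L]]),
                                     rowLogSumExp(lKh[[1L]], lg))
                   else rowLogSumExp(lKh[[1L]], lg)
            dev <- max(dev, pmax(1 - exp(la + ls0), 0))
            if (S1 > 0L) {
                lS <- rep(-Inf, n)
                for (s in seq_len(S1)) {
                    I <- inSumL(s); O <- outSumL(s)
                    dev <- max(dev, abs(exp(lw[[s]] + I) -
                                        exp(lb - lw[[s]] + O)))
                    lS <- lse2(lS, O - lw[[s]])
                }
                dev <- max(dev, pmax(1 - exp(lb + lS), 0))
            }
            lgin <- colLogSumExp(lKh[[1L]], la)
            if (S1 > 0L) for (s in 2:Tn)
                lgin <- lse2(lgin, colLogSumExp(lKh[[s]], lb - lw[[s - 1L]]))
            dev <- max(dev, pmax(1 - exp(lg + lgin), 0))
            if (max(dmax, dev) < tol)
                return(list(la = la, lb = lb, lw = lw, lg = lg,
                            iterations = it, residual = max(dmax, dev),
                            converged = TRUE))
        }
    }
    list(la = la, lb = lb, lw = lw, lg = lg, iterations = maxIters,
         residual = NA_real_, converged = FALSE)
}

## Internal: assemble cost block lists from a CostSet for T stages.
.costBlocks <- function(costs, Tn, n) {
    if (n == 0L) return(list(Ct = list(), Ch = list(costs@C0F)))
    Ct <- c(list(costs@C0X), rep(list(costs@CXX), max(Tn - 2L, 0L)))
    Ch <- c(list(costs@C0F), rep(list(costs@CXF), Tn - 1L))
    list(Ct = Ct, Ch = Ch)
}

#' Solve the entropy-regularized multistage transport problem
#'
#' One generalized Sinkhorn solve at regularization `config@epsilonStart`,
#' optionally relative to a prior (the Kullback-Leibler proximal step used
#' by [proximalSolve()]).  Mass flows from the initial tier through the
#' intermediate tier over `T` stages and exits to the terminal tier; every
#' initial cell must emit, every intermediate cell must handle, and every
#' terminal cell must receive at least one unit of mass.  All mass reaching
#' the final stage exits to the terminal tier.
#'
#' @param costs a [CostSet-class].
#' @param partition the matching [StatePartition-class].
#' @param config an [MsotConfig-class]; only `epsilonStart`, `nStages`,
#'   `tolTau`, `maxInnerIters` and `logDomain` are used here.
#' @param prior optional [StagePlans-class] of matching shapes used as the
#'   entropic prior.
#' @return `list(plans = StagePlans, report = SolveReport)`.
#' @seealso [proximalSolve()] for the production entry point.
#' @export
solveMsotEntropic <- function(costs, partition, config, prior = NULL) {
    stopifnot(is(costs, "CostSet"), is(partition, "StatePartition"),
              is(config, "MsotConfig"))
    n0 <- length(partition@X0); n <- length(partition@X)
    nF <- length(partition@XF)
    if (nrow(costs@C0X) != n0 || ncol(costs@C0X) != n ||
        ncol(costs@C0F) != nF)
        stop("cost set dimensions do not match the partition")
    Tn <- config@nStages
    eps <- config@epsilonStart
    blocks <- .costBlocks(costs, Tn, n)
    labels <- list(initial = partition@cellIds[partition@X0],
                   intermediate = partition@cellIds[partition@X],
                   terminal = partition@cellIds[partition@XF])

    if (config@logDomain) {
        lKt <- lapply(blocks$Ct, function(C) -C / eps)
        lKh <- lapply(blocks$Ch, function(C) -C / eps)
        if (!is.null(prior)) {
            lKt <- mapply(function(lk, p) lk + log(p), lKt, prior@Mtilde,
                          SIMPLIFY = FALSE)
            lKh <- mapply(function(lk, p) lk + log(p), lKh, prior@Mhat,
                          SIMPLIFY = FALSE)
        }
        st <- .msotScaleLog(lKt, lKh, eps, config@tolTau,
                            config@maxInnerIters, labels)
        S1 <- length(lKt)
        rowT <- function(s) if (s == 1L) st$la else st$lb - st$lw[[s - 1L]]
        Mtilde <- lapply(seq_len(S1), function(s)
            exp(lKt[[s]] + outer(rowT(s), st$lw[[s]], "+")))
        Mhat <- lapply(seq_along(lKh), function(s)
            exp(lKh[[s]] + outer(rowT(s), st$lg, "+")))
    } else {
        Kt <- lapply(blocks$Ct, function(C) exp(-C / eps))
        Kh <- lapply(blocks$Ch, function(C) exp(-C / eps))
        if (!is.null(prior)) {
            Kt <- mapply(`*`, Kt, prior@Mtilde, SIMPLIFY = FALSE)
            Kh <- mapply(`*`, Kh, prior@Mhat, SIMPLIFY = FALSE)
        }
        st <- .msotScale(Kt, Kh, eps, config@tolTau, config@maxInnerIters,
                         labels)
        S1 <- length(Kt)
        rowS <- function(s) if (s == 1L) st$a else st$b / st$w[[s - 1L]]
        Mtilde <- lapply(seq_len(S1), function(s)
            Kt[[s]] * outer(rowS(s), st$w[[s]]))
        Mhat <- lapply(seq_along(Kh), function(s)
            Kh[[s]] * outer(rowS(s), st$g))
    }

    plans <- new("StagePlans", Mtilde = Mtilde, Mhat = Mhat,
                 nStages = Tn)
    cost <- 0
    for (s in seq_along(Mtilde))
        cost <- cost + sum(blocks$Ct[[s]] * Mtilde[[s]])
    for (s in seq_along(Mhat))
        cost <- cost + sum(blocks$Ch[[s]] * Mhat[[s]])
    report <- new("SolveReport", converged = st$converged,
                  innerIterations = as.integer(st$iterations),
                  proxStepsDone = 1L,
                  finalResidual = if (is.na(st$residual)) Inf else st$residual,
                  transportCost = cost, effectiveEpsilon = eps)
    list(plans = plans, report = report)
}

#' Solve the multistage transport problem with proximal regularization
#' annealing
#'
#' Repeats [solveMsotEntropic()] with the previous round's plans as the
#' entropic prior (Kullback-Leibler proximal point scheme).  After `k`
#' rounds the effective regularization is `epsilonStart / k`, so a moderate,
#' numerically safe starting value anneals to the small regularization that
#' sharp transport plans require.
#'
#' @inheritParams solveMsotEntropic
#' @return `list(plans = StagePlans, report = SolveReport)`; the report
#'   accumulates sweep counts per round and sets
#'   `effectiveEpsilon = epsilonStart / proxStepsDone`.  If a round fails to
#'   converge the scheme stops there and returns the last iterate with
#'   `converged = FALSE`.
#' @examples
#' sim <- makeBranchingSnapshot(skeletonSpec(nCells = 60, seed = 1))
#' costs <- normalizeCosts(computeCosts(sim$snapshot, sim$partition))
#' fit <- proximalSolve(costs, sim$partition,
#'                      msotConfig(nStages = 5, proxIters = 2,
#'                                 maxInnerIters = 5000))
#' fit$report
#' @export
proximalSolve <- function(costs, partition, config) {
    stopifnot(is(config, "MsotConfig"))
    prior <- NULL
    iters <- integer()
    res <- NULL
    for (k in seq_len(config@proxIters)) {
        res <- tryCatch(
            solveMsotEntropic(costs, partition, config, prior = prior),
            error = function(e) e)
        if (inherits(res, "error")) {
            ## deep annealing can underflow the multiplicative kernels;
            ## continue with log-domain stabilized updates in that case
            if (!config@logDomain &&
                grepl("numerical instability", conditionMessage(res))) {
                config@logDomain <- TRUE
                res <- solveMsotEntropic(costs, partition, config,
                                         prior = prior)
            } else stop(res)
        }
        iters <- c(iters, res$report@innerIterations)
        if (!res$report@converged) {
            rep <- res$report
            rep@innerIterations <- iters
            rep@proxStepsDone <- k
            rep@effectiveEpsilon <- config@epsilonStart / k
            warning("proximal round ", k, " did not converge within ",
                    config@maxInnerIters, " sweeps; returning partial result")
            return(list(plans = res$plans, report = rep))
        }
        prior <- res$plans
    }
    rep <- res$report
    rep@innerIterations <- iters
    rep@proxStepsDone <- config@proxIters
    rep@effectiveEpsilon <- config@epsilonStart / config@proxIters
    list(plans = res$plans, report = rep)
}

#' Constraint residuals of stagewise plans
#'
#' Recomputes, from the plan matrices alone, the maximum absolute
#' stage-coupling residual and the maximum violation of each of the three
#' unit lower bounds (zero when satisfied).
#'
#' @param plans a [StagePlans-class].
#' @param partition the matching [StatePartition-class].
#' @return `list(coupling, initial, throughput, terminal, max)`.
#' @export
constraintResiduals <- function(plans, partition) {
    stopifnot(is(plans, "StagePlans"), is(partition, "StatePartition"))
    n0 <- length(partition@X0); n <- length(partition@X)
    nF <- length(partition@XF)
    Tn <- plans@nStages
    S1 <- length(plans@Mtilde)
    if (length(plans@Mhat) < 1L ||
        nrow(plans@Mhat[[1L]]) != n0 || ncol(plans@Mhat[[1L]]) != nF ||
        (S1 > 0L && ncol(plans@Mtilde[[1L]]) != n))
        stop("plan shapes do not match the partition")

    coupling <- 0
    if (S1 > 0L) {
        for (s in seq_len(S1)) {
            inflow <- colSums(plans@Mtilde[[s]])
            outflow <- rowSums(plans@Mhat[[s + 1L]])
            if (s < S1) outflow <- outflow + rowSums(plans@Mtilde[[s + 1L]])
            coupling <- max(coupling, abs(inflow - outflow))
        }
    }
    initial <- max(0, 1 - (rowSums(plans@Mhat[[1L]]) +
                           if (S1 > 0L) rowSums(plans@Mtilde[[1L]]) else 0))
    throughput <- 0
    if (S1 > 0L) {
        tot <- rep(0, n)
        for (s in seq_len(S1)) {
            if (s >= 2L) tot <- tot + rowSums(plans@Mtilde[[s]])
            tot <- tot + rowSums(plans@Mhat[[s + 1L]])
        }
        throughput <- max(0, 1 - tot)
    }
    recv <- Reduce(`+`, lapply(plans@Mhat, colSums))
    terminal <- max(0, 1 - recv)
    list(coupling = coupling, initial = initial, throughput = throughput,
         terminal = terminal,
         max = max(coupling, initial, throughput, terminal))
}
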