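## Independent oracles used across the suite.

## Generic LP solve (min c'x, A x <= b, Aeq x = beq, x >= 0) through the
## system python's scipy (HiGHS) -- an implementation entirely independent
## of the package's Sinkhorn solver.
lpSolveOracle <- function(cc, A = NULL, b = NULL, Aeq = NULL, beq = NULL) {
    infile <- tempfile(fileext = ".json")
    outfile <- tempfile(fileext = ".json")
    jsonlite::write_json(list(c = cc, A = A, b = b, Aeq = Aeq, beq = beq),
                         infile, digits = NA, matrix = "rowmajor",
                         null = "null")
    script <- c(
        "import sys, json, numpy as np",
        "from scipy.optimize import linprog",
        "d = json.load(open(sys.argv[1]))",
        "kw = dict(c=np.array(d['c']), bounds=(0, None), method='highs')",
        "if d.get('A'): kw['A_ub']=np.array(d['A']); kw['b_ub']=np.array(d['b'])",
        "if d.get('Aeq'): kw['A_eq']=np.array(d['Aeq']); kw['b_eq']=np.array(d['beq'])",
        "r = linprog(**kw)",
        "json.dump({'fun': r.fun, 'status': int(r.status), 'x': list(r.x)},",
        "          open(sys.argv[2], 'w'))")
    sf <- tempfile(fileext = ".py")
    writeLines(script, sf)
    st <- system2("python", c(sf, infile, outfile), stdout = TRUE,
                  stderr = TRUE)
    if (!file.exists(outfile))
        stop("LP oracle failed: ", paste(st, collapse = "\n"))
    res <- jsonlite::read_json(outfile, simplifyVector = TRUE)
    if (res$status != 0) stop("LP oracle status ", res$status)
    res
}

## LP formulation of the multistage program on the flow polytope, matching
## the solver's constraint set exactly (variables = stacked plan entries).
msotLP <- function(costs, part, Tn) {
    n0 <- length(part@X0); n <- length(part@X); nF <- length(part@XF)
    dims <- list()
    dims$Mt <- if (n > 0) c(list(c(n0, n)), rep(list(c(n, n)), Tn - 2))
               else list()
    dims$Mh <- c(list(c(n0, nF)),
                 if (n > 0) rep(list(c(n, nF)), Tn - 1) else list())
    sizes <- c(vapply(dims$Mt, prod, 1), vapply(dims$Mh, prod, 1))
    nv <- sum(sizes); off <- cumsum(c(0, sizes)); nMt <- length(dims$Mt)
    idxMt <- function(s) off[s] + seq_len(prod(dims$Mt[[s]]))
    idxMh <- function(s) off[nMt + s] + seq_len(prod(dims$Mh[[s]]))
    cc <- numeric(nv)
    Cb <- msot:::.costBlocks(costs, Tn, n)
    for (s in seq_len(nMt)) cc[idxMt(s)] <- as.vector(Cb$Ct[[s]])
    for (s in seq_along(dims$Mh)) cc[idxMh(s)] <- as.vector(Cb$Ch[[s]])
    rowSumMat <- function(d) kronecker(t(rep(1, d[2])), diag(d[1]))
    colSumMat <- function(d) kronecker(diag(d[2]), t(rep(1, d[1])))
    Aeq <- NULL; beq <- NULL
    if (n > 0) for (s in seq_len(Tn - 1)) {
        row <- matrix(0, n, nv)
        row[, idxMt(s)] <- colSumMat(dims$Mt[[s]])
        if (s + 1 <= nMt)
            row[, idxMt(s + 1)] <- -rowSumMat(dims$Mt[[s + 1]])
        row[, idxMh(s + 1)] <- row[, idxMh(s + 1)] -
            rowSumMat(dims$Mh[[s + 1]])
        Aeq <- rbind(Aeq, row); beq <- c(beq, rep(0, n))
    }
    A <- NULL; b <- NULL
    r0 <- matrix(0, n0, nv)
    if (n > 0) r0[, idxMt(1)] <- rowSumMat(dims$Mt[[1]])
    r0[, idxMh(1)] <- r0[, idxMh(1)] + rowSumMat(dims$Mh[[1]])
    A <- rbind(A, -r0); b <- c(b, rep(-1, n0))
    if (n > 0) {
        rx <- matrix(0, n, nv)
        for (s in seq_len(nMt)) if (s >= 2)
            rx[, idxMt(s)] <- rx[, idxMt(s)] + rowSumMat(dims$Mt[[s]])
        for (s in 2:Tn)
            rx[, idxMh(s)] <- rx[, idxMh(s)] + rowSumMat(dims$Mh[[s]])
        A <- rbind(A, -rx); b <- c(b, rep(-1, n))
    }
    rf <- matrix(0, nF, nv)
    for (s in seq_along(dims$Mh))
        rf[, idxMh(s)] <- rf[, idxMh(s)] + colSumMat(dims$Mh[[s]])
    A <- rbind(A, -rf); b <- c(b, rep(-1, nF))
    lpSolveOracle(cc, A = A, b = b, Aeq = Aeq, beq = beq)
}
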