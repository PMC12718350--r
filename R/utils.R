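## Internal helpers.

## Evaluate `code` under a fixed RNG state without disturbing the caller's
## stream (the generator functions promise bitwise determinism given a seed).
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

## log(sum(exp(.))) over rows of L + rep(v, each = nrow): v indexed by column.
rowLogSumExp <- function(L, v = NULL) {
    if (!is.null(v)) L <- L + rep(v, each = nrow(L))
    m <- apply(L, 1L, max)
    m[!is.finite(m)] <- 0   # all -Inf row -> log-sum -Inf, handled below
    r <- m + log(rowSums(exp(L - m)))
    r[apply(L, 1L, function(z) all(z == -Inf))] <- -Inf
    r
}

colLogSumExp <- function(L, v = NULL) {
    if (!is.null(v)) L <- L + v
    rowLogSumExp(t(L))
}

## Squared Euclidean distances between rows of A and rows of B.
sqDist <- function(A, B) {
    a2 <- rowSums(A^2)
    b2 <- rowSums(B^2)
    d <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
    d[d < 0] <- 0  # numerical noise
    d
}

## Stable file writing: fixed 15-significant-digit formatting so repeated
## runs are byte-identical across platforms.
writeResultCsv <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 15,
                                                   format = "g"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
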