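## Internal numerical helpers shared across modules.

## Squared Euclidean distances between rows of X (n x 3) and Y (m x 3).
.pairdist2 <- function(X, Y) {
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
    d2[d2 < 0] <- 0
    d2
}

## Cancellation-free variant: accumulates squared coordinate differences
## directly, so identical points give exactly 0 (the expansion above loses
## ~eps * scale^2). Used where exact zeros matter (vertex distances).
.pairdist2exact <- function(X, Y) {
    d2 <- (outer(X[, 1], Y[, 1], "-"))^2
    d2 <- d2 + (outer(X[, 2], Y[, 2], "-"))^2
    d2 + (outer(X[, 3], Y[, 3], "-"))^2
}

## Gaussian kernel matrix K_ij = exp(-|x_i - y_j|^2 / (2 sigma^2)).
.kernelMatrix <- function(X, Y, sigma) {
    exp(-.pairdist2(X, Y) / (2 * sigma^2))
}

## Deterministic per-stage seed derived from a master seed. Lehmer-style
## mixing keeps the result a valid 32-bit R seed and makes stages
## independent of each other and of call order.
.stageSeed <- function(seed, stage) {
    s <- (as.numeric(seed) %% 2147483646) + 1
    for (k in seq_len(stage %% 64 + 1)) s <- (s * 48271) %% 2147483647
    as.integer((s + stage) %% 2147483647)
}

## Evaluate an expression with a local RNG state (restores .Random.seed).
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}
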