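## Shared fixtures, built in code at test time.

## unit tetrahedron used across I/O tests
tetraSurface <- function() {
    triSurface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               rbind(c(0L, 1L, 2L), c(0L, 1L, 3L), c(0L, 2L, 3L),
                     c(1L, 2L, 3L)))
}

## hand-written ASCII OFF of the same tetrahedron
tetraOFFLines <- function() {
    c("OFF", "4 4 0",
      "0 0 0", "1 0 0", "0 1 0", "0 0 1",
      "3 0 1 2", "3 0 1 3", "3 0 2 3", "3 1 2 3")
}

## small icosphere template (42 vertices) for fast geometry tests
smallSpec <- function(...) syntheticSpec(subdivisions = 1L, ...)

smallTemplate <- function() makeTemplate(smallSpec())

## a modest ground-truth prior on the small template
smallPrior <- function(seed = 3L, spectrumScale = 25, nModes = 4L) {
    makeGroundTruthPrior(smallSpec(seed = seed, nModes = nModes,
                                   spectrumScale = spectrumScale))
}

## brute-force O(n^2) symmetric vertex Hausdorff distance (oracle)
bruteHausdorff <- function(A, B) {
    VA <- if (is(A, "TriSurface")) vertices(A) else A
    VB <- if (is(B, "TriSurface")) vertices(B) else B
    dmin <- function(X, Y) {
        vapply(seq_len(nrow(X)), function(i)
            min(sqrt(colSums((t(Y) - X[i, ])^2))), numeric(1))
    }
    max(max(dmin(VA, VB)), max(dmin(VB, VA)))
}

## independent oracle for the reverse water-filling rate: enumerate every
## possible submerged set (the k smallest variances), solve the water
## level in closed form for each split, and keep the consistent one
oracleWaterfillRate <- function(variances, D) {
    v <- sort(variances)
    B <- length(v)
    if (D >= sum(v)) return(0)
    for (k in 0:(B - 1L)) {
        lam <- (D - sum(v[seq_len(k)])) / (B - k)
        loOK <- k == 0L || v[k] <= lam + 1e-12
        hiOK <- lam <= v[k + 1L] + 1e-12
        if (loOK && hiOK) {
            Di <- pmin(lam, v)
            pos <- v > Di
            return(sum(0.5 * log2(v[pos] / Di[pos])))
        }
    }
    stop("oracle failed to locate a consistent water level")
}

## kernel Gram matrix of a vertex set (test-side, independent route)
testKernelMatrix <- function(X, sigma) {
    exp(-as.matrix(dist(X))^2 / (2 * sigma^2))
}
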