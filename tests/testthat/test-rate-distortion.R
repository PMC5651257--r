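test_that("single-Gaussian rate follows the closed form with a zero branch", {
    expect_equal(rdRateSingle(4, 4), 0)           # D = sigma^2 boundary
    expect_equal(rdRateSingle(1, 4), 1)           # half log2(4)
    expect_equal(rdRateSingle(8, 4), 0)           # D > sigma^2: one codeword
    expect_equal(rdRateSingle(0.25, 1), 1)
    expect_error(rdRateSingle(0, 1), "D")
})

test_that("reverse water-filling solves the worked two-dimension example", {
    wf <- reverseWaterfill(c(4, 1), 2)
    expect_equal(wf@lambda, 1, tolerance = 1e-9)
    expect_equal(wf@perDimDistortion, c(1, 1), tolerance = 1e-9)
    expect_equal(rateBits(wf), 1, tolerance = 1e-9)
    ## total-variance boundary: rate 0, everything submerged
    wf0 <- reverseWaterfill(c(4, 1), 5)
    expect_equal(wf0@lambda, 4)
    expect_equal(rateBits(wf0), 0)
    ## single dimension collapses to the closed form
    expect_equal(rateOfDistortion(2.5, 0.5), rdRateSingle(0.5, 2.5),
                 tolerance = 1e-9)
})

test_that("water-filling conserves distortion and matches a grid oracle", {
    set.seed(31)
    for (trial in seq_len(25L)) {
        vars <- runif(sample(2:10, 1L), 0.05, 5)
        D <- runif(1L, 0.02, sum(vars) * 0.99)
        wf <- reverseWaterfill(vars, D)
        expect_lt(abs(sum(wf@perDimDistortion) - D), 1e-9 * max(1, D))
        expect_equal(rateBits(wf), oracleWaterfillRate(vars, D),
                     tolerance = 1e-9)
    }
})

test_that("R(D) is non-increasing and convex on a scanned grid", {
    vars <- c(4, 2.5, 1, 0.4, 0.1)
    Ds <- seq(0.05, sum(vars) * 0.999, length.out = 60L)
    Rs <- vapply(Ds, function(D) rateOfDistortion(vars, D), numeric(1))
    expect_true(all(diff(Rs) <= 1e-12))
    expect_true(all(diff(diff(Rs)) >= -1e-9))
    ## continuity at the total-variance boundary
    expect_lt(rateOfDistortion(vars, sum(vars) * (1 - 1e-9)), 1e-6)
})

test_that("the water level for a target rate inverts Eq-6 exactly", {
    lf <- lambdaForRate(c(4, 1), 1)
    expect_equal(lf@lambda, 1, tolerance = 1e-6)
    expect_equal(lf@totalDistortion, 2, tolerance = 1e-6)
    lf0 <- lambdaForRate(c(4, 1), 0)
    expect_equal(lf0@perDimDistortion, c(4, 1))
    set.seed(17)
    for (trial in seq_len(20L)) {
        vars <- runif(sample(2:8, 1L), 0.05, 5)
        R <- runif(1L, 0, 12)
        wf <- lambdaForRate(vars, R)
        expect_equal(rateBits(wf), R, tolerance = 1e-9)
        expect_equal(rateOfDistortion(vars, wf@totalDistortion), R,
                     tolerance = 1e-6)
    }
})

test_that("codebooks have the prescribed size, sparsity and determinism", {
    prior0 <- smallPrior()
    cb0 <- makeCodebook(prior0, 0L, seed = 2L)
    expect_equal(codebookSize(cb0), 1)
    expect_true(all(cb0@codewords == 0))    # R = 0 decodes to the mean
    cb4 <- makeCodebook(prior0, 4L, seed = 2L)
    expect_equal(codebookSize(cb4), 16)     # a four-bit code
    expect_identical(cb4@codewords,
                     makeCodebook(prior0, 4L, seed = 2L)@codewords)
    ## components below the water line are exactly zero in every codeword
    lam <- cb4@lambda
    dead <- variances(prior0) < lam
    if (any(dead))
        expect_true(all(cb4@codewords[, dead] == 0))
    ## with a large codebook the live components match N(0, sigma_i^2 -
    ## lambda) in sample variance
    vars <- c(1, 0.5, 1 / 3, 0.25)
    cb10 <- makeCodebook(vars, 10L, seed = 3L)   # 1024 codewords
    lam10 <- cb10@lambda
    live10 <- vars >= lam10
    sv <- apply(cb10@codewords[, live10, drop = FALSE], 2L, var)
    expect_equal(sv, vars[live10] - lam10, tolerance = 0.2)
    expect_error(makeCodebook(prior0, 25L), "cap")
})

test_that("encoding is exhaustive nearest-codeword search", {
    prior0 <- smallPrior()
    cb <- makeCodebook(prior0, 0L, seed = 1L)
    expect_equal(encodeCoefficients(rnorm(nModes(prior0)), cb), 0L)
    set.seed(23)
    cb3 <- makeCodebook(c(2, 1, 0.5), 2L, seed = 5L)   # 4 codewords
    for (k in seq_len(codebookSize(cb3))) {
        expect_equal(encodeCoefficients(cb3@codewords[k, ], cb3), k - 1L)
    }
    for (trial in seq_len(50L)) {
        beta <- rnorm(3, sd = 2)
        d2 <- rowSums(sweep(cb3@codewords, 2L, beta)^2)   # brute force
        expect_equal(encodeCoefficients(beta, cb3), which.min(d2) - 1L)
    }
    expect_error(encodeCoefficients(rnorm(5), cb3), "dimension")
})

test_that("decoding returns stored codewords and rejects bad indices", {
    cb <- makeCodebook(c(2, 1), 3L, seed = 9L)
    for (k in c(0L, 3L, 7L))
        expect_equal(decodeCoefficients(k, cb), cb@codewords[k + 1L, ])
    beta <- cb@codewords[5L, ]
    expect_equal(decodeCoefficients(encodeCoefficients(beta, cb), cb), beta)
    expect_error(decodeCoefficients(8L, cb), "out of range")
    expect_error(decodeCoefficients(-1L, cb), "out of range")
})

test_that("empirical distortion behaves like the Gaussian theory says", {
    ## samples identical to codewords: zero distortion
    cb <- makeCodebook(c(2, 1, 0.5), 2L, seed = 4L)
    expect_equal(empiricalDistortion(cb@codewords, cb), 0)
    ## R = 0: the single mean codeword has expected distortion = variance
    vars <- c(1, 0.5, 1 / 3, 0.25, 0.2)
    cb0 <- makeCodebook(vars, 0L, seed = 6L)
    samp <- withr::with_seed(42, {
        matrix(rnorm(5000 * 5), 5000, 5) %*% diag(sqrt(vars))
    })
    expect_equal(empiricalDistortion(samp, cb0), sum(vars),
                 tolerance = 0.05)
    ## block coding normalizes per structure: N = 2 at R = 0 also ~ sum(vars)
    cbN2 <- makeCodebook(vars, 0L, N = 2L, seed = 6L)
    sampN2 <- cbind(samp[1:2500, ], samp[2501:5000, ])
    expect_equal(empiricalDistortion(sampN2, cbN2), sum(vars),
                 tolerance = 0.05)
})
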