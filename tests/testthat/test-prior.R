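test_that("kernel inner product matches hand-expanded Gram sums", {
    one <- matrix(c(0, 0, 0), 1, 3)
    ex <- matrix(c(1, 0, 0), 1, 3)
    expect_equal(kernelInner(ex, ex, one), 1)          # K(0) = 1
    expect_equal(kernelInner(ex, 0 * ex, one), 0)
    ## two vertices at distance d, unit x-momenta on both:
    ## <p, p>_K = 2 + 2 exp(-d^2 / 2 sigma^2)
    for (d in c(1, 4, 9)) {
        pts <- rbind(c(0, 0, 0), c(d, 0, 0))
        p <- rbind(c(1, 0, 0), c(1, 0, 0))
        expect_equal(kernelInner(p, p, pts),
                     2 + 2 * exp(-d^2 / (2 * 6.5^2)))
    }
    ## symmetry and bilinearity on random fields
    set.seed(4)
    X <- vertices(smallTemplate())
    p <- matrix(rnorm(3 * nrow(X)), ncol = 3)
    q <- matrix(rnorm(3 * nrow(X)), ncol = 3)
    expect_equal(kernelInner(p, q, X), kernelInner(q, p, X))
    expect_equal(kernelInner(2 * p + q, q, X),
                 2 * kernelInner(p, q, X) + kernelInner(q, q, X))
})

test_that("trace-fraction mode selection follows the cumulative spectrum", {
    ## construct a population whose kernel-metric sample covariance has
    ## exactly the eigenvalue shares (0.90, 0.05, 0.04, 0.01): with the
    ## 95% cut the prior must retain B = 2 modes
    prior0 <- smallPrior(nModes = 4L)
    tmpl <- priorTemplate(prior0)
    shares <- c(0.90, 0.05, 0.04, 0.01)
    M <- 5L
    H <- stats::contr.helmert(M)               # orthogonal, zero-mean cols
    C <- sweep(H[, 1:4], 2L, sqrt(colSums(H[, 1:4]^2)), `/`)
    C <- sweep(C, 2L, sqrt((M - 1) * shares), `*`)  # exact sample covariance
    pop <- lapply(seq_len(M), function(m)
        reconstructMomentum(C[m, ], prior0))
    fit <- fitPrior(pop, tmpl, kernelSpec(6.5), traceFraction = 0.95)
    expect_equal(nModes(fit), 2L)
    expect_equal(variances(fit), c(0.90, 0.05), tolerance = 1e-8)
})

test_that("two-sample PCA reduces to the single nonzero eigenvalue", {
    prior0 <- smallPrior()
    tmpl <- priorTemplate(prior0)
    p1 <- reconstructMomentum(c(2, 0, 0, 0), prior0)
    p2 <- reconstructMomentum(c(-1, 1, 0, 0), prior0)
    fit <- fitPrior(list(p1, p2), tmpl, kernelSpec(6.5))
    expect_equal(nModes(fit), 1L)
    d2 <- kernelInner(momenta(p1) - momenta(p2),
                      momenta(p1) - momenta(p2), vertices(tmpl))
    expect_equal(variances(fit), d2 / 2, tolerance = 1e-8)
})

test_that("fitted bases are kernel-orthonormal and capture the trace", {
    prior0 <- smallPrior()
    pop <- makePopulation(prior0, 40, seed = 21)
    fit <- fitPrior(pop, priorTemplate(prior0), kernelSpec(6.5),
                    traceFraction = 0.95)
    X <- vertices(priorTemplate(prior0))
    B <- nModes(fit)
    G <- outer(seq_len(B), seq_len(B),
               Vectorize(function(i, j)
                   kernelInner(priorBasis(fit)[[i]], priorBasis(fit)[[j]],
                               X)))
    expect_lt(max(abs(G - diag(B))), 1e-8)
    ## Parseval at fit: retained variance covers the trace fraction
    Zc <- t(vapply(pop, function(p) {
        R <- chol(testKernelMatrix(X, 6.5))
        as.vector(R %*% momenta(p))
    }, numeric(3 * nrow(X))))
    Zc <- sweep(Zc, 2L, colMeans(Zc))
    total <- sum(Zc^2) / (length(pop) - 1)
    expect_gte(sum(variances(fit)) + 1e-9, 0.95 * total)
    expect_lte(sum(variances(fit)), total * (1 + 1e-9))
})

test_that("projection and reconstruction invert each other in span", {
    prior0 <- smallPrior()
    B <- nModes(prior0)
    expect_equal(projectMomentum(priorMean(prior0), prior0), rep(0, B))
    beta1 <- c(2.5, rep(0, B - 1L))
    expect_equal(projectMomentum(reconstructMomentum(beta1, prior0), prior0),
                 beta1, tolerance = 1e-8)
    set.seed(2)
    beta <- rnorm(B)
    p <- reconstructMomentum(beta, prior0)
    expect_equal(projectMomentum(p, prior0), beta, tolerance = 1e-8)
    expect_equal(momenta(reconstructMomentum(projectMomentum(p, prior0),
                                             prior0)),
                 momenta(p), tolerance = 1e-8)
    expect_error(reconstructMomentum(rep(0, B + 1L), prior0), "coefficients")
})

test_that("prior sampling is seeded and matches its variances", {
    prior0 <- smallPrior()
    expect_identical(samplePrior(prior0, 5, seed = 8),
                     samplePrior(prior0, 5, seed = 8))
    s <- samplePrior(prior0, 20000, seed = 13)
    relerr <- abs(apply(s, 2L, var) - variances(prior0)) / variances(prior0)
    expect_lt(relerr[1], 0.05)        # CLT: sd of sample var ~ sqrt(2/n)
    expect_true(all(abs(colMeans(s)) < 3 * sqrt(variances(prior0) / 20000)))
})

test_that("degenerate populations are rejected", {
    prior0 <- smallPrior()
    p <- reconstructMomentum(c(1, 0, 0, 0), prior0)
    expect_error(fitPrior(list(p), priorTemplate(prior0)), "at least 2")
    expect_error(fitPrior(list(p, p), priorTemplate(prior0)),
                 "zero total variance")
})

test_that("prior directory serialization roundtrips", {
    prior0 <- smallPrior()
    dir <- withr::local_tempdir()
    savePrior(prior0, dir)
    back <- loadPrior(dir)
    expect_equal(vertices(priorTemplate(back)),
                 vertices(priorTemplate(prior0)))
    expect_identical(momenta(priorMean(back)), momenta(priorMean(prior0)))
    expect_equal(variances(back), variances(prior0), tolerance = 1e-12)
    expect_identical(momenta(priorBasis(back)[[2]]),
                     momenta(priorBasis(prior0)[[2]]))
    expect_equal(kernelSigma(back), 6.5)
})
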