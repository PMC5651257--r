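test_that("rate-error curves are reproducible and anchored at the mean", {
    prior <- smallPrior()
    curve <- rateErrorExperiment(prior, rates = c(0L, 2L, 4L), nObs = 6L,
                                 seed = 11L)
    curve2 <- rateErrorExperiment(prior, rates = c(0L, 2L, 4L), nObs = 6L,
                                  seed = 11L)
    expect_identical(curve@meanErrorMm, curve2@meanErrorMm)
    expect_identical(curve@stderrMm, curve2@stderrMm)

    ## the rate-0 entry is the mean Hausdorff distance between sampled
    ## shapes and the decoded mean shape (recomputed independently from
    ## the experiment's per-stage seed)
    sampleSeed <- morphocode:::.stageSeed(11L, 3L)  # stage of rate index 1
    samp <- samplePrior(prior, 6L, seed = sampleSeed)
    tmpl <- priorTemplate(prior)
    meanShape <- deformed(shootGeodesic(tmpl, priorMean(prior)))
    errs <- vapply(seq_len(6L), function(i) {
        s <- shootGeodesic(tmpl, reconstructMomentum(samp[i, ], prior))
        hausdorffDistance(deformed(s), meanShape)
    }, numeric(1))
    expect_equal(curve@meanErrorMm[1L], mean(errs), tolerance = 1e-12)
})

test_that("a planted exponential curve is inverted exactly", {
    ## err(R) = 4 * 2^(-0.5 R) + 0.5 must give R = 4 at target 1.5
    R <- seq(0, 12, by = 2)
    err <- 4 * 2^(-0.5 * R) + 0.5
    curve <- new("RateErrorCurve", rateBits = R, meanErrorMm = err,
                 stderrMm = rep(0.01, length(R)), nObs = 10L,
                 blockSize = 1L, seed = 1L)
    fit <- fitRateAtError(curve, 1.5)
    expect_equal(rateBits(fit), 4, tolerance = 1e-4)
    expect_false(fit@fitParams$fallback)
    expect_equal(fit@fitParams$a, 4, tolerance = 1e-4)
    expect_equal(fit@fitParams$b, 0.5, tolerance = 1e-4)
    expect_equal(fit@fitParams$c, 0.5, tolerance = 1e-4)
    ## analytic inversion of the generating formula at another target
    expect_equal(rateBits(fitRateAtError(curve, 2.5)),
                 -log2((2.5 - 0.5) / 4) / 0.5, tolerance = 1e-4)
})

test_that("targets above the mean-shape error clamp the rate to zero", {
    R <- seq(0, 10, by = 2)
    err <- 2 * 2^(-0.4 * R) + 0.3
    curve <- new("RateErrorCurve", rateBits = R, meanErrorMm = err,
                 stderrMm = rep(0.01, length(R)), nObs = 10L,
                 blockSize = 1L, seed = 1L)
    expect_equal(rateBits(fitRateAtError(curve, 5)), 0)   # mean suffices
    expect_equal(rateBits(fitRateAtError(curve, err[1L] + 0.01)), 0)
    ## a target below the fitted floor is unreachable on this curve
    expect_error(fitRateAtError(curve, 0.2), "unreachable")
})

test_that("tighter accuracy always needs at least as many bits", {
    set.seed(8)
    for (trial in seq_len(5L)) {
        R <- seq(0, 12, by = 2)
        a <- runif(1, 1, 6); b <- runif(1, 0.2, 0.8); c0 <- runif(1, 0.1, 0.6)
        err <- a * 2^(-b * R) + c0 + rnorm(length(R), sd = 0.01)
        curve <- new("RateErrorCurve", rateBits = R,
                     meanErrorMm = pmax(err, 0.01),
                     stderrMm = rep(0.01, length(R)), nObs = 10L,
                     blockSize = 1L, seed = 1L)
        r10 <- rateBits(fitRateAtError(curve, 1.0))
        r15 <- rateBits(fitRateAtError(curve, 1.5))
        expect_gte(r10, r15)
    }
})

test_that("the interpolation fallback is monotone and flagged", {
    ## a curve no decaying exponential fits (non-monotone noise) still
    ## yields a rate via monotone interpolation
    R <- c(0, 2, 4, 6)
    err <- c(3, 1.2, 1.3, 0.6)
    curve <- new("RateErrorCurve", rateBits = R, meanErrorMm = err,
                 stderrMm = rep(0.1, 4L), nObs = 5L, blockSize = 1L,
                 seed = 1L)
    fit <- fitRateAtError(curve, 1.0)
    expect_gte(rateBits(fit), 0)
    expect_true(is.finite(rateBits(fit)))
})
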