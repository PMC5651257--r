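test_that("Gaussian kernel has unit peak and the analytic profile", {
    expect_identical(gaussKernel(c(0, 0, 0)), 1)
    expect_equal(gaussKernel(c(6.5, 0, 0)), exp(-0.5))      # |dx| = sigma
    expect_equal(gaussKernel(c(3, 4, 0), kernelSpec(5)), exp(-0.5))
    ## default bandwidth is the 6.5 mm modeling scale
    expect_equal(kernelSigma(kernelSpec()), 6.5)
})

test_that("velocity field is the kernel-weighted momentum sum", {
    pts <- rbind(c(0, 0, 0), c(3, 0, 0))
    p <- rbind(c(1, 2, 0), c(0, -1, 1))
    expect_equal(velocityField(c(5, 1, 2), pts, 0 * p), c(0, 0, 0))
    expect_equal(velocityField(pts[1, ], pts[1, , drop = FALSE],
                               p[1, , drop = FALSE]), p[1, ])
    ## two particles at distance d: v(x_1) = p_1 + exp(-d^2/2sigma^2) p_2
    w <- exp(-9 / (2 * 6.5^2))
    expect_equal(velocityField(pts[1, ], pts, p), p[1, ] + w * p[2, ])
    expect_error(velocityField(c(0, 0, 0), pts, p[1, , drop = FALSE]),
                 "same number")
})

test_that("zero momentum gives the identity flow bit-for-bit", {
    tmpl <- smallTemplate()
    res <- shootGeodesic(tmpl, momentumField(matrix(0, nVertices(tmpl), 3)))
    expect_identical(vertices(deformed(res)), vertices(tmpl))
    expect_identical(faces(deformed(res)), faces(tmpl))
    expect_true(all(hamiltonianTrace(res) == 0))
})

test_that("a single particle travels in a straight line by its momentum", {
    ## grad K(0) = 0 keeps the momentum constant, so the one-particle
    ## geodesic is x(1) = x(0) + p
    start <- c(1, -2, 0.5); p <- c(2, -1, 3)
    surf <- triSurface(matrix(start, 1, 3))
    res <- shootGeodesic(surf, momentumField(matrix(p, 1, 3)), nSteps = 10L)
    expect_equal(as.numeric(vertices(deformed(res))), start + p,
                 tolerance = 1e-10)
    h <- hamiltonianTrace(res)
    expect_equal(h, rep(0.5 * sum(p^2), 11L), tolerance = 1e-12)
})

test_that("the Hamiltonian is conserved and drift shrinks at RK4 order", {
    prior <- smallPrior()
    beta <- samplePrior(prior, 1, seed = 5)
    pMod <- reconstructMomentum(beta[1, ], prior)   # ~few-mm displacement
    tmpl <- priorTemplate(prior)
    res <- shootGeodesic(tmpl, pMod, kernelSpec(6.5), nSteps = 10L)
    h <- hamiltonianTrace(res)
    expect_length(h, 11L)
    expect_lt(max(abs(h - h[1])) / abs(h[1]), 1e-3)

    ## order check on stiffer momenta where drift is well above roundoff
    pBig <- momentumField(3 * momenta(pMod))
    drift <- vapply(c(10L, 20L), function(ns) {
        hh <- hamiltonianTrace(shootGeodesic(tmpl, pBig, kernelSpec(6.5),
                                             nSteps = ns))
        max(abs(hh - hh[1])) / abs(hh[1])
    }, numeric(1))
    expect_gt(drift[1] / drift[2], 8)    # ~16x for an O(h^4) scheme
})

test_that("small momenta linearize: displacement ~ eps * v at t = 1", {
    prior <- smallPrior()
    tmpl <- priorTemplate(prior)
    pm <- momenta(reconstructMomentum(samplePrior(prior, 1, seed = 9)[1, ],
                                      prior))
    v0 <- velocityField(vertices(tmpl), vertices(tmpl), pm)
    eps <- 1e-3
    res <- shootGeodesic(tmpl, momentumField(eps * pm))
    disp <- vertices(deformed(res)) - vertices(tmpl)
    expect_lt(max(abs(disp - eps * v0)), 10 * eps^2 * max(abs(v0)))
})

test_that("mismatched momenta and diverging integrations are diagnosed", {
    tmpl <- smallTemplate()
    expect_error(shootGeodesic(tmpl, momentumField(matrix(0, 5, 3))),
                 "vertices")
    huge <- momentumField(matrix(1e200, nVertices(tmpl), 3))
    expect_error(shootGeodesic(tmpl, huge, nSteps = 2L), "step")
})
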