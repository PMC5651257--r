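#' @include AllClasses.R accessors.R shooting.R
NULL

## The momentum space at the template carries the kernel (dual-space)
## metric <p, q>_K = sum_ab p_a' K(x_a - x_b) q_b. Because the kernel is
## scalar-times-identity, the 3n x 3n Gram operator factors as K (x) I_3
## and every metric computation reduces to the n x n kernel matrix.

.asMomentumMatrix <- function(p) {
    if (is(p, "MomentumField")) p@values else as.matrix(p)
}

## Upper Cholesky factor of the kernel Gram matrix, with a single 1e-10
## jitter retry when the matrix is numerically singular (dense meshes at
## large sigma).
.kernelChol <- function(points, sigma) {
    K <- .kernelMatrix(points, points, sigma)
    tryCatch(chol(K), error = function(e) {
        message("kernel Gram matrix numerically singular; adding 1e-10 jitter")
        chol(K + diag(1e-10, nrow(K)))
    })
}

#' Kernel inner product of two momentum fields
#'
#' Evaluates the dual-space (RKHS) bilinear form
#' `<p, q>_K = sum_ab p_a' K(x_a - x_b) q_b`, the double sum over template
#' vertex pairs weighted by the Gaussian kernel. This is the metric under
#' which prior basis modes are orthonormal.
#'
#' @param p,q [MomentumField-class] objects (or `n x 3` matrices).
#' @param points template vertex coordinates (`n x 3` matrix or a
#'   [TriSurface-class]).
#' @param kernel a [KernelSpec-class].
#' @return numeric(1).
#' @export
kernelInner <- function(p, q, points, kernel = kernelSpec()) {
    P <- .asMomentumMatrix(p); Q <- .asMomentumMatrix(q)
    if (is(points, "TriSurface")) points <- points@vertices
    if (nrow(P) != nrow(points) || nrow(Q) != nrow(points))
        stop("momentum fields and template must have the same vertex count")
    K <- .kernelMatrix(points, points, kernel@sigma)
    sum(P * (K %*% Q))
}

#' Fit an empirical Gaussian shape prior by kernel-metric PCA
#'
#' Tangent-space PCA of a population of initial momentum fields under the
#' kernel inner product. The computation whitens each field through the
#' Cholesky factor of the kernel Gram matrix (`K = R'R`, `z = vec(R P)`),
#' runs standard PCA on the whitened vectors, and maps principal
#' directions back through `R^-1`, which makes the returned basis
#' kernel-orthonormal by construction. The number of retained modes `B` is
#' the smallest count whose cumulative variance reaches `traceFraction` of
#' the total kernel-metric variance; eigenvalues below `1e-12` times the
#' leading one are discarded first (rank deficiency when the sample is
#' smaller than the ambient dimension).
#'
#' @param momenta list of [MomentumField-class] (>= 2), all matching the
#'   template.
#' @param template a [TriSurface-class].
#' @param kernel a [KernelSpec-class].
#' @param traceFraction fraction of the covariance trace to retain
#'   (default 0.95).
#' @return a [ShapePrior-class] with mean `b0`, kernel-orthonormal basis
#'   and non-increasing positive variances (sample covariance divisor
#'   `M - 1`).
#' @seealso [projectMomentum()], [reconstructMomentum()], [samplePrior()]
#' @export
fitPrior <- function(momenta, template, kernel = kernelSpec(),
                     traceFraction = 0.95) {
    stopifnot(is(template, "TriSurface"))
    M <- length(momenta)
    if (M < 2L) stop("need at least 2 momentum fields to fit a prior")
    n <- nVertices(template)
    mats <- lapply(momenta, .asMomentumMatrix)
    if (any(vapply(mats, nrow, 0L) != n))
        stop("all momentum fields must match the template vertex count")

    R <- .kernelChol(template@vertices, kernel@sigma)
    Z <- t(vapply(mats, function(P) as.vector(R %*% P), numeric(3L * n)))
    zbar <- colMeans(Z)
    Zc <- sweep(Z, 2L, zbar)
    sv <- svd(Zc, nu = 0)
    eig <- sv$d^2 / (M - 1)
    total <- sum(eig)
    if (total <= 0) stop("zero total variance: all momentum fields identical")
    keep <- eig > 1e-12 * eig[1L]
    eig <- eig[keep]
    V <- sv$v[, keep, drop = FALSE]
    B <- which(cumsum(eig) >= traceFraction * total)[1L]
    if (is.na(B)) B <- length(eig)

    b0 <- Reduce(`+`, mats) / M
    basis <- lapply(seq_len(B), function(i) {
        U <- matrix(V[, i], n, 3L)
        momentumField(backsolve(R, U))
    })
    new("ShapePrior", template = template, kernel = kernel,
        b0 = momentumField(b0), basis = basis, variances = eig[seq_len(B)],
        traceFraction = traceFraction)
}

#' Project a momentum field onto a prior's basis
#'
#' Returns the coefficients `beta_i = <p - b0, b_i>_K` of the centered
#' field in the kernel-orthonormal basis. For fields lying in the basis
#' span, [reconstructMomentum()] inverts this exactly.
#'
#' @param p a [MomentumField-class] matching the prior's template.
#' @param prior a [ShapePrior-class].
#' @return numeric(B) coefficient vector.
#' @export
projectMomentum <- function(p, prior) {
    P <- .asMomentumMatrix(p)
    X <- prior@template@vertices
    if (nrow(P) != nrow(X))
        stop("momentum field does not match the prior's template")
    K <- .kernelMatrix(X, X, prior@kernel@sigma)
    Pc <- P - prior@b0@values
    KP <- K %*% Pc
    vapply(prior@basis, function(b) sum(b@values * KP), numeric(1))
}

#' Reconstruct a momentum field from coefficients
#'
#' Returns `b0 + sum_i beta_i b_i`.
#'
#' @param beta numeric(B) coefficient vector.
#' @param prior a [ShapePrior-class].
#' @return a [MomentumField-class].
#' @export
reconstructMomentum <- function(beta, prior) {
    B <- length(prior@basis)
    if (length(beta) != B)
        stop(sprintf("expected %d coefficients, got %d", B, length(beta)))
    vals <- prior@b0@values
    for (i in seq_len(B)) vals <- vals + beta[i] * prior@basis[[i]]@values
    momentumField(vals)
}

#' Sample coefficient vectors from the prior
#'
#' Independent draws `beta_i ~ N(0, sigma_i^2)` per retained mode.
#'
#' @param prior a [ShapePrior-class].
#' @param n number of draws.
#' @param seed RNG seed (draws are reproducible; the caller's RNG state is
#'   left untouched).
#' @return numeric matrix `n x B`, one coefficient vector per row.
#' @export
samplePrior <- function(prior, n, seed = 1L) {
    stopifnot(n >= 1L)
    sd <- sqrt(prior@variances)
    .withSeed(seed, {
        matrix(stats::rnorm(n * length(sd)), n, length(sd), byrow = TRUE) *
            rep(sd, each = n)
    })
}

#' Save / load a shape prior as a directory
#'
#' The on-disk layout is plain text plus flat binaries: `template.ply`
#' (binary PLY), `b0.bin` and `basis_###.bin` momentum binaries with JSON
#' sidecars, and `metadata.json` holding `sigma`, `variances` and
#' `trace_fraction`.
#'
#' @param prior a [ShapePrior-class].
#' @param dir directory path (created if needed).
#' @return `savePrior`: invisibly, the directory; `loadPrior`: a
#'   [ShapePrior-class].
#' @export
savePrior <- function(prior, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeSurface(prior@template, file.path(dir, "template.ply"),
                 format = "PLY")
    writeMomenta(prior@b0, file.path(dir, "b0.bin"))
    for (i in seq_along(prior@basis))
        writeMomenta(prior@basis[[i]],
                     file.path(dir, sprintf("basis_%03d.bin", i)))
    jsonlite::write_json(
        list(sigma = prior@kernel@sigma, variances = prior@variances,
             trace_fraction = prior@traceFraction,
             n_modes = length(prior@basis)),
        file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' @rdname savePrior
#' @export
loadPrior <- function(dir) {
    meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                                simplifyVector = TRUE)
    template <- readSurface(file.path(dir, "template.ply"))
    n <- nVertices(template)
    b0 <- readMomenta(file.path(dir, "b0.bin"), vertexCount = n)
    basis <- lapply(seq_len(meta$n_modes), function(i)
        readMomenta(file.path(dir, sprintf("basis_%03d.bin", i)),
                    vertexCount = n))
    new("ShapePrior", template = template,
        kernel = kernelSpec(meta$sigma), b0 = b0, basis = basis,
        variances = as.numeric(meta$variances),
        traceFraction = meta$trace_fraction)
}
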