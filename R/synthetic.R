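#' @include AllClasses.R accessors.R prior.R
NULL

## Synthetic study generator: a smooth template, kernel-orthonormal
## momentum modes and a decaying variance spectrum with known ground
## truth, emulating the structure of an empirical subcortical shape prior
## so the whole pipeline can be validated without external data.

.icosahedron <- function() {
    phi <- (1 + sqrt(5)) / 2
    V <- rbind(
        c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
        c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
        c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
    V <- V / sqrt(1 + phi^2)
    F <- rbind(
        c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
        c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
        c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
        c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
    list(V = V, F = F)
}

## One 4-to-1 triangle subdivision with midpoint vertices projected back
## to the unit sphere; preserves the consistent outward orientation of
## the base icosahedron.
.subdivideSphere <- function(V, F) {
    key <- function(i, j) paste(min(i, j), max(i, j))
    mid <- new.env(hash = TRUE)
    verts <- lapply(seq_len(nrow(V)), function(i) V[i, ])
    midpoint <- function(i, j) {
        k <- key(i, j)
        if (!is.null(mid[[k]])) return(mid[[k]])
        m <- (verts[[i + 1L]] + verts[[j + 1L]]) / 2
        m <- m / sqrt(sum(m^2))
        verts[[length(verts) + 1L]] <<- m
        mid[[k]] <- length(verts) - 1L
        mid[[k]]
    }
    newF <- matrix(0L, 4L * nrow(F), 3L)
    for (t in seq_len(nrow(F))) {
        a <- F[t, 1L]; b <- F[t, 2L]; c <- F[t, 3L]
        ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
        newF[(4L * (t - 1L) + 1L):(4L * t), ] <- rbind(
            c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    list(V = do.call(rbind, verts), F = newF)
}

#' Generate a synthetic template surface
#'
#' A `subdivisions`-times subdivided icosahedron (level k has
#' `10 * 4^k + 2` vertices and `20 * 4^k` faces), scaled by the spec's
#' semi-axes. The default 20 x 12 x 10 mm extent is hippocampus-like. The
#' mesh is watertight and consistently outward-oriented.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [TriSurface-class].
#' @examples
#' nVertices(makeTemplate(syntheticSpec(subdivisions = 2L)))  # 162
#' @export
makeTemplate <- function(spec = syntheticSpec()) {
    stopifnot(is(spec, "SyntheticSpec"))
    m <- .icosahedron()
    for (k in seq_len(spec@subdivisions)) m <- .subdivideSphere(m$V, m$F)
    V <- sweep(m$V, 2L, spec@semiAxes, `*`)
    triSurface(V, m$F)
}

#' Generate a ground-truth shape prior
#'
#' Draws `nModes` smooth momentum fields (kernel-smoothed white noise on
#' the template vertices), orthonormalizes them under the kernel inner
#' product by Gram-Schmidt (redrawing on numerical breakdown), and
#' attaches the power-law spectrum `sigma_i^2 = s * i^(-gamma)`. The mean
#' momentum `b0` is zero by default, so the template is the mean shape;
#' `meanMomentum` plants a nonzero mean for testing mean handling.
#'
#' @param spec a [SyntheticSpec-class].
#' @param meanMomentum optional [MomentumField-class] used as `b0`.
#' @return a [ShapePrior-class] with known ground truth.
#' @export
makeGroundTruthPrior <- function(spec = syntheticSpec(),
                                 meanMomentum = NULL) {
    stopifnot(is(spec, "SyntheticSpec"))
    template <- makeTemplate(spec)
    n <- nVertices(template)
    if (spec@nModes > 3L * n)
        stop("nModes cannot exceed 3 x vertex count")
    kernel <- kernelSpec(spec@sigma)
    X <- template@vertices
    K <- .kernelMatrix(X, X, spec@sigma)

    basis <- .withSeed(spec@seed, {
        out <- vector("list", spec@nModes)
        i <- 1L
        while (i <= spec@nModes) {
            cand <- K %*% matrix(stats::rnorm(3L * n), n, 3L)
            for (b in out[seq_len(i - 1L)])
                cand <- cand - kernelInner(cand, b, X, kernel) * b
            nrm <- kernelInner(cand, cand, X, kernel)
            if (nrm < 1e-10) {
                message("Gram-Schmidt breakdown; redrawing mode")
                next
            }
            out[[i]] <- cand / sqrt(nrm)
            i <- i + 1L
        }
        out
    })

    variances <- spec@spectrumScale * seq_len(spec@nModes)^(-spec@spectrumDecay)
    b0 <- if (is.null(meanMomentum)) momentumField(matrix(0, n, 3L))
          else meanMomentum
    new("ShapePrior", template = template, kernel = kernel, b0 = b0,
        basis = lapply(basis, momentumField), variances = variances,
        traceFraction = 1)
}

#' Sample a synthetic subject population
#'
#' Draws `nSubjects` momentum fields `b0 + sum_i beta_i b_i` with
#' independent `beta_i ~ N(0, sigma_i^2)` from a (ground-truth or fitted)
#' prior. The fields can be written with [writeMomenta()] and are
#' indistinguishable from an externally supplied momentum population.
#'
#' @param prior a [ShapePrior-class].
#' @param nSubjects number of subjects (>= 2).
#' @param seed RNG seed.
#' @return list of [MomentumField-class], with the generating coefficient
#'   matrix attached as attribute `"beta"` (the per-subject ground truth).
#' @export
makePopulation <- function(prior, nSubjects, seed = 1L) {
    stopifnot(is(prior, "ShapePrior"), nSubjects >= 2L)
    beta <- samplePrior(prior, nSubjects, seed = seed)
    pop <- lapply(seq_len(nSubjects), function(m)
        reconstructMomentum(beta[m, ], prior))
    attr(pop, "beta") <- beta
    pop
}
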