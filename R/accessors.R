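#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a TriSurface
#'
#' @param vertices numeric matrix `n x 3` of coordinates in mm.
#' @param faces integer matrix `m x 3` of 0-based vertex indices (may have
#'   zero rows for point sets used in low-level computations).
#' @return a [TriSurface-class].
#' @examples
#' tet <- triSurface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'                   rbind(c(0, 1, 2), c(0, 1, 3), c(0, 2, 3), c(1, 2, 3)))
#' nVertices(tet)
#' @export
triSurface <- function(vertices, faces = matrix(integer(0), 0L, 3L)) {
    vertices <- as.matrix(vertices)
    storage.mode(vertices) <- "double"
    faces <- as.matrix(faces)
    if (nrow(faces) > 0L) storage.mode(faces) <- "integer"
    else faces <- matrix(integer(0), 0L, 3L)
    new("TriSurface", vertices = vertices, faces = faces)
}

#' Construct a MomentumField
#'
#' @param values numeric matrix `n x 3`, one momentum 3-vector per template
#'   vertex, or a length-`3n` vector (reshaped column-major as `n x 3`).
#' @return a [MomentumField-class].
#' @export
momentumField <- function(values) {
    if (is.null(dim(values))) {
        if (length(values) %% 3L != 0L)
            stop("momentum vector length must be a multiple of 3")
        values <- matrix(values, ncol = 3L)
    }
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("MomentumField", values = values)
}

#' Construct a KernelSpec
#'
#' @param sigma Gaussian kernel standard deviation in mm (default 6.5, the
#'   bandwidth used for subcortical shape modeling).
#' @return a [KernelSpec-class].
#' @export
kernelSpec <- function(sigma = 6.5) new("KernelSpec", sigma = sigma)

#' Construct a SyntheticSpec
#'
#' Defaults describe a hippocampus-like synthetic study: a twice-subdivided
#' icosphere (162 vertices) scaled to 20 x 12 x 10 mm semi-axes, 5
#' ground-truth modes with spectrum `sigma_i^2 = s / i`, and the 6.5 mm
#' kernel. The default `spectrumScale` is chosen so that typical shape
#' displacements are a few millimeters (see the package vignette).
#'
#' @param templateKind `"icosphere"` or `"ellipsoid"`.
#' @param subdivisions icosphere subdivision level (level k has
#'   `10 * 4^k + 2` vertices).
#' @param semiAxes numeric(3), template semi-axes in mm.
#' @param nModes number of ground-truth variance modes.
#' @param spectrumScale `s` in `sigma_i^2 = s * i^(-gamma)`.
#' @param spectrumDecay `gamma` in the spectrum rule.
#' @param sigma kernel standard deviation in mm.
#' @param seed generator seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(templateKind = "icosphere", subdivisions = 2L,
                          semiAxes = c(20, 12, 10), nModes = 5L,
                          spectrumScale = 25, spectrumDecay = 1,
                          sigma = 6.5, seed = 1L) {
    new("SyntheticSpec", templateKind = templateKind,
        subdivisions = as.integer(subdivisions), semiAxes = semiAxes,
        nModes = as.integer(nModes), spectrumScale = spectrumScale,
        spectrumDecay = spectrumDecay, sigma = sigma,
        seed = as.integer(seed))
}

## ---- accessors -----------------------------------------------------------

#' @rdname vertices
#' @export
setMethod("vertices", "TriSurface", function(x) x@vertices)

#' @rdname faces
#' @export
setMethod("faces", "TriSurface", function(x) x@faces)

#' @rdname nVertices
#' @export
setMethod("nVertices", "TriSurface", function(x) nrow(x@vertices))

#' @rdname nVertices
#' @export
setMethod("nVertices", "MomentumField", function(x) nrow(x@values))

#' @rdname momenta
#' @export
setMethod("momenta", "MomentumField", function(x) x@values)

#' @rdname kernelSigma
#' @export
setMethod("kernelSigma", "KernelSpec", function(x) x@sigma)

#' @rdname kernelSigma
#' @export
setMethod("kernelSigma", "ShapePrior", function(x) x@kernel@sigma)

#' @rdname variances
#' @export
setMethod("variances", "ShapePrior", function(x) x@variances)

#' @rdname variances
#' @export
setMethod("variances", "Codebook", function(x) x@variances)

#' @rdname nModes
#' @export
setMethod("nModes", "ShapePrior", function(x) length(x@basis))

#' Template surface of a prior
#'
#' @param prior a [ShapePrior-class].
#' @return the [TriSurface-class] template.
#' @export
priorTemplate <- function(prior) prior@template

#' Mean momentum field of a prior
#'
#' @param prior a [ShapePrior-class].
#' @return a [MomentumField-class].
#' @export
priorMean <- function(prior) prior@b0

#' Basis modes of a prior
#'
#' @param prior a [ShapePrior-class].
#' @return list of [MomentumField-class], kernel-orthonormal.
#' @export
priorBasis <- function(prior) prior@basis

#' @rdname rateBits
#' @export
setMethod("rateBits", "Codebook", function(x) x@rateBits)

#' @rdname rateBits
#' @export
setMethod("rateBits", "WaterfillSolution", function(x) x@rateBits)

#' @rdname rateBits
#' @export
setMethod("rateBits", "RateErrorCurve", function(x) x@rateBits)

#' @rdname rateBits
#' @export
setMethod("rateBits", "RateAtScale", function(x) x@rateBits)

#' @rdname codebookSize
#' @export
setMethod("codebookSize", "Codebook", function(x) nrow(x@codewords))

#' Deformed surface from a shooting result
#'
#' @param x a [ShootingResult-class].
#' @return the deformed [TriSurface-class].
#' @export
deformed <- function(x) x@deformed

#' Hamiltonian trace from a shooting result
#'
#' @param x a [ShootingResult-class].
#' @return numeric vector, length `nSteps + 1`.
#' @export
hamiltonianTrace <- function(x) x@hamiltonianTrace

#' Summarize a rate-error curve as a data.frame
#'
#' @param curve a [RateErrorCurve-class].
#' @return data.frame with columns `rate_bits`, `mean_error_mm`,
#'   `stderr_mm`.
#' @export
asRateErrorTable <- function(curve) {
    data.frame(rate_bits = curve@rateBits,
               mean_error_mm = curve@meanErrorMm,
               stderr_mm = curve@stderrMm)
}

## ---- show methods --------------------------------------------------------

setMethod("show", "TriSurface", function(object) {
    cat(sprintf("TriSurface: %d vertices, %d faces\n",
                nrow(object@vertices), nrow(object@faces)))
    rng <- apply(object@vertices, 2L, range)
    cat(sprintf("  extent (mm): [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2],
                rng[1, 3], rng[2, 3]))
})

setMethod("show", "MomentumField", function(object) {
    nrm <- sqrt(rowSums(object@values^2))
    cat(sprintf("MomentumField: %d vertices, |p| in [%.3g, %.3g]\n",
                nrow(object@values), min(nrm), max(nrm)))
})

setMethod("show", "KernelSpec", function(object) {
    cat(sprintf("KernelSpec: Gaussian, sigma = %g mm\n", object@sigma))
})

setMethod("show", "ShapePrior", function(object) {
    cat(sprintf(paste0("ShapePrior: %d modes on a %d-vertex template ",
                       "(sigma = %g mm, %.0f%% trace)\n"),
                length(object@basis), nrow(object@template@vertices),
                object@kernel@sigma, 100 * object@traceFraction))
    v <- object@variances
    cat(sprintf("  variances: %s%s\n",
                paste(signif(utils::head(v, 5L), 4), collapse = ", "),
                if (length(v) > 5L) ", ..." else ""))
})

setMethod("show", "WaterfillSolution", function(object) {
    cat(sprintf(paste0("WaterfillSolution: lambda = %.6g, D = %.6g, ",
                       "R = %.6g bits (%d dims)\n"),
                object@lambda, object@totalDistortion, object@rateBits,
                length(object@perDimDistortion)))
})

setMethod("show", "Codebook", function(object) {
    cat(sprintf(paste0("Codebook: R = %d bits/structure, N = %d, ",
                       "%d codewords in R^%d (lambda = %.4g)\n"),
                object@rateBits, object@blockSize, nrow(object@codewords),
                ncol(object@codewords), object@lambda))
})

setMethod("show", "RateErrorCurve", function(object) {
    cat(sprintf("RateErrorCurve: N = %d, %d obs/rate\n",
                object@blockSize, object@nObs))
    print(asRateErrorTable(object), row.names = FALSE)
})

setMethod("show", "RateAtScale", function(object) {
    cat(sprintf("RateAtScale: %.3g bits required at %.2f mm\n",
                object@rateBits, object@targetMm))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(paste0("SyntheticSpec: %s (subdiv %d, semi-axes %s mm), ",
                       "%d modes, sigma_i^2 = %g * i^-%g, kernel %g mm\n"),
                object@templateKind, object@subdivisions,
                paste(object@semiAxes, collapse = "x"), object@nModes,
                object@spectrumScale, object@spectrumDecay, object@sigma))
})
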