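#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' TriSurface: a triangulated surface
#'
#' Container for a triangle mesh in millimeter coordinates: an `n x 3`
#' numeric matrix of vertex positions and an `m x 3` integer matrix of
#' 0-based vertex indices, one row per triangle. Vertex order is semantic
#' throughout the package (momentum fields are vertex-indexed), so no
#' operation ever permutes it.
#'
#' @slot vertices numeric matrix, `n x 3`, vertex coordinates in mm.
#' @slot faces integer matrix, `m x 3`, 0-based vertex indices.
#'
#' @seealso [triSurface()], [readSurface()], [writeSurface()]
#' @exportClass TriSurface
setClass("TriSurface",
    representation(vertices = "matrix", faces = "matrix"),
    validity = function(object) {
        v <- object@vertices
        f <- object@faces
        if (!is.numeric(v) || ncol(v) != 3L)
            return("'vertices' must be a numeric matrix with 3 columns")
        if (nrow(v) < 1L)
            return("surface must have at least one vertex")
        if (!all(is.finite(v)))
            return("vertex coordinates must be finite")
        if (ncol(f) != 3L && nrow(f) > 0L)
            return("'faces' must have 3 columns")
        if (nrow(f) > 0L) {
            if (!all(f == round(f)))
                return("face indices must be integers")
            if (min(f) < 0L || max(f) >= nrow(v))
                return(sprintf("face index out of range [0, %d)", nrow(v)))
        }
        TRUE
    })

#' MomentumField: initial momenta attached to template vertices
#'
#' One 3-vector per template vertex. A momentum field parameterizes a
#' diffeomorphic deformation of the template via geodesic shooting
#' ([shootGeodesic()]): it determines the initial velocity field through the
#' Gaussian kernel and is transported along the flow by the Hamiltonian
#' particle system.
#'
#' @slot values numeric matrix, `n x 3`, one momentum vector per vertex.
#'
#' @seealso [momentumField()], [shootGeodesic()], [readMomenta()]
#' @exportClass MomentumField
setClass("MomentumField",
    representation(values = "matrix"),
    validity = function(object) {
        v <- object@values
        if (!is.numeric(v) || ncol(v) != 3L)
            return("'values' must be a numeric matrix with 3 columns")
        if (nrow(v) < 1L)
            return("momentum field must have at least one vertex")
        if (!all(is.finite(v)))
            return("momentum entries must be finite")
        TRUE
    })

#' KernelSpec: Gaussian kernel parameters
#'
#' The velocity-field kernel is the unnormalized isotropic Gaussian
#' `K(dx) = exp(-|dx|^2 / (2 sigma^2))` with `K(0) = 1`; the kernel is
#' scalar times the identity (no curl/divergence components). The default
#' bandwidth is 6.5 mm, the scale at which subcortical shape variation is
#' modeled.
#'
#' @slot sigma numeric(1), kernel standard deviation in mm; must be > 0.
#'
#' @seealso [kernelSpec()], [gaussKernel()]
#' @exportClass KernelSpec
setClass("KernelSpec",
    representation(sigma = "numeric"),
    prototype(sigma = 6.5),
    validity = function(object) {
        if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
            object@sigma <= 0)
            return("'sigma' must be a single positive finite number")
        TRUE
    })

#' ShootingResult: outcome of geodesic shooting
#'
#' @slot deformed [TriSurface-class], the template carried to t = 1 (same
#'   face list as the template).
#' @slot trajectory list or NULL; when stored, per-step lists with elements
#'   `x` and `p` (vertex positions and momenta).
#' @slot hamiltonianTrace numeric, value of the Hamiltonian
#'   `H = 1/2 sum_ij p_i' K(x_i - x_j) p_j` at each of the `nSteps + 1`
#'   time points; conserved along exact geodesics, so its drift measures
#'   integration error.
#'
#' @seealso [shootGeodesic()]
#' @exportClass ShootingResult
setClass("ShootingResult",
    representation(deformed = "TriSurface", trajectory = "listOrNULL",
                   hamiltonianTrace = "numeric"))

#' ShapePrior: empirical Gaussian prior on initial momenta
#'
#' Tangent-space PCA model of a population of momentum fields: a mean field
#' `b0`, a basis of momentum modes orthonormal under the kernel
#' (dual-space) inner product, and per-mode variances in descending order.
#' A random shape is `b0 + sum_i beta_i b_i` with independent
#' `beta_i ~ N(0, sigma_i^2)`.
#'
#' @slot template [TriSurface-class] the momenta are attached to.
#' @slot kernel [KernelSpec-class] defining the metric and the shooting
#'   velocity field.
#' @slot b0 [MomentumField-class], population mean momentum.
#' @slot basis list of B [MomentumField-class] modes, kernel-orthonormal.
#' @slot variances numeric(B), strictly positive, non-increasing.
#' @slot traceFraction numeric(1), fraction of total covariance trace the
#'   retained modes account for.
#'
#' @seealso [fitPrior()], [samplePrior()], [projectMomentum()]
#' @exportClass ShapePrior
setClass("ShapePrior",
    representation(template = "TriSurface", kernel = "KernelSpec",
                   b0 = "MomentumField", basis = "list",
                   variances = "numeric", traceFraction = "numeric"),
    validity = function(object) {
        B <- length(object@basis)
        if (B < 1L)
            return("prior must retain at least one mode")
        if (length(object@variances) != B)
            return("length(variances) must equal length(basis)")
        if (any(!is.finite(object@variances)) || any(object@variances <= 0))
            return("variances must be strictly positive")
        if (is.unsorted(rev(object@variances)))
            return("variances must be non-increasing")
        n <- nrow(object@template@vertices)
        ok <- vapply(object@basis, function(b)
            is(b, "MomentumField") && nrow(b@values) == n, logical(1))
        if (!all(ok))
            return("every basis element must be a MomentumField matching the template")
        if (nrow(object@b0@values) != n)
            return("b0 must match the template vertex count")
        TRUE
    })

#' WaterfillSolution: reverse water-filling allocation
#'
#' For independent Gaussians with variances `sigma_i^2` and a total
#' distortion budget `D`, reverse water-filling assigns per-dimension
#' distortion `D_i = min(lambda, sigma_i^2)` with the water level `lambda`
#' chosen so that `sum(D_i) = D`; the achievable rate is
#' `R(D) = sum_i 1/2 log2(sigma_i^2 / D_i)` bits.
#'
#' @slot lambda numeric(1), water level (variance units).
#' @slot perDimDistortion numeric, the `D_i`.
#' @slot rateBits numeric(1), `R(D)` in bits (>= 0).
#' @slot totalDistortion numeric(1), `sum(D_i)`.
#'
#' @seealso [reverseWaterfill()], [lambdaForRate()]
#' @exportClass WaterfillSolution
setClass("WaterfillSolution",
    representation(lambda = "numeric", perDimDistortion = "numeric",
                   rateBits = "numeric", totalDistortion = "numeric"),
    validity = function(object) {
        if (object@rateBits < 0)
            return("rateBits must be non-negative")
        if (abs(sum(object@perDimDistortion) - object@totalDistortion) >
            1e-9 * max(1, object@totalDistortion))
            return("per-dimension distortions must sum to totalDistortion")
        TRUE
    })

#' Codebook: a random rate-distortion code for shape coefficients
#'
#' A set of `2^(N * R)` codewords in coefficient space, drawn once from the
#' water-filled Gaussian `N(0, sigma_i^2 - lambda)` per retained dimension
#' (dimensions with `sigma_i^2 < lambda` are exactly 0 in every codeword).
#' `N` is the block size: the number of independent structure instances
#' coded simultaneously, each contributing `B` coefficients.
#'
#' @slot rateBits integer(1), rate R per structure in bits.
#' @slot blockSize integer(1), N.
#' @slot lambda numeric(1), water level used for sampling.
#' @slot codewords numeric matrix, `2^(N*R) x (N*B)`.
#' @slot variances numeric(B), the per-structure prior variances.
#' @slot seed integer(1), RNG seed the codewords are reproducible from.
#' @slot priorId character(1), identifier of the generating prior.
#'
#' @seealso [makeCodebook()], [encodeCoefficients()], [decodeCoefficients()]
#' @exportClass Codebook
setClass("Codebook",
    representation(rateBits = "integer", blockSize = "integer",
                   lambda = "numeric", codewords = "matrix",
                   variances = "numeric", seed = "integer",
                   priorId = "character"),
    validity = function(object) {
        size <- 2^(as.numeric(object@rateBits) * object@blockSize)
        if (nrow(object@codewords) != size)
            return("codebook must contain 2^(N*R) codewords")
        if (ncol(object@codewords) !=
            object@blockSize * length(object@variances))
            return("codeword dimension must equal N * B")
        TRUE
    })

#' RateErrorCurve: geometric error as a function of code rate
#'
#' Per-rate mean and standard error of the Hausdorff distance (mm) between
#' sampled shapes and their discretely coded versions, both realized as
#' deformed surfaces by geodesic shooting.
#'
#' @slot rateBits numeric, strictly increasing rate grid.
#' @slot meanErrorMm numeric, mean Hausdorff error per rate.
#' @slot stderrMm numeric, standard error per rate.
#' @slot nObs integer(1), observations per rate.
#' @slot blockSize integer(1), block size N used.
#' @slot seed integer(1), master seed of the experiment.
#'
#' @seealso [rateErrorExperiment()], [fitRateAtError()]
#' @exportClass RateErrorCurve
setClass("RateErrorCurve",
    representation(rateBits = "numeric", meanErrorMm = "numeric",
                   stderrMm = "numeric", nObs = "integer",
                   blockSize = "integer", seed = "integer"),
    validity = function(object) {
        k <- length(object@rateBits)
        if (length(object@meanErrorMm) != k || length(object@stderrMm) != k)
            return("rateBits, meanErrorMm, stderrMm must have equal length")
        if (k > 1 && any(diff(object@rateBits) <= 0))
            return("rates must be strictly increasing")
        if (any(object@stderrMm < 0))
            return("standard errors must be non-negative")
        TRUE
    })

#' RateAtScale: code rate required at a target geometric accuracy
#'
#' @slot targetMm numeric(1), geometric error target in mm (e.g. 1.0, 1.5).
#' @slot rateBits numeric(1), fitted rate (>= 0; 0 when the mean shape
#'   alone already meets the target).
#' @slot fitParams list, the fitted curve parameters (`a`, `b`, `c` of
#'   `err(R) = a 2^(-bR) + c`, or the interpolation fallback record).
#'
#' @seealso [fitRateAtError()]
#' @exportClass RateAtScale
setClass("RateAtScale",
    representation(targetMm = "numeric", rateBits = "numeric",
                   fitParams = "list"),
    validity = function(object) {
        if (object@rateBits < 0) return("rateBits must be non-negative")
        TRUE
    })

#' SyntheticSpec: parameters of the synthetic shape population generator
#'
#' Describes a ground-truth shape model standing in for a real
#' template/momentum population: a subdivided-icosahedron template scaled
#' to hippocampus-like extent, `nModes` kernel-orthonormal momentum modes
#' built from kernel-smoothed white noise, and a power-law variance
#' spectrum `sigma_i^2 = s * i^(-gamma)`.
#'
#' @slot templateKind character(1), `"icosphere"` or `"ellipsoid"` (both
#'   are subdivided icosahedra; `"ellipsoid"` emphasizes anisotropic axes).
#' @slot subdivisions integer(1), icosphere subdivision level.
#' @slot semiAxes numeric(3), template semi-axes in mm.
#' @slot nModes integer(1), number of ground-truth modes.
#' @slot spectrumScale numeric(1), `s` in `sigma_i^2 = s * i^(-gamma)`.
#' @slot spectrumDecay numeric(1), `gamma`.
#' @slot sigma numeric(1), kernel standard deviation in mm.
#' @slot seed integer(1), generator seed.
#'
#' @seealso [syntheticSpec()], [makeTemplate()], [makeGroundTruthPrior()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(templateKind = "character", subdivisions = "integer",
                   semiAxes = "numeric", nModes = "integer",
                   spectrumScale = "numeric", spectrumDecay = "numeric",
                   sigma = "numeric", seed = "integer"),
    validity = function(object) {
        if (!object@templateKind %in% c("icosphere", "ellipsoid"))
            return("templateKind must be 'icosphere' or 'ellipsoid'")
        if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0))
            return("semiAxes must be 3 positive values (mm)")
        if (object@nModes < 1L)
            return("nModes must be >= 1")
        if (object@spectrumScale <= 0)
            return("spectrumScale must be > 0")
        if (object@subdivisions < 0L)
            return("subdivisions must be >= 0")
        if (object@sigma <= 0)
            return("sigma must be > 0")
        TRUE
    })
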