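#' @include AllClasses.R accessors.R prior.R rate-distortion.R metrics.R shooting.R
NULL

#' Geometric error as a function of code rate
#'
#' For each rate on the grid: build the random codebook, draw `nObs`
#' blocks of coefficient vectors from the prior, encode each block to its
#' nearest codeword, realize both the sampled momentum and the decoded
#' codeword momentum as surfaces by geodesic shooting, and record the
#' Hausdorff distance between the two deformed surfaces. With block size
#' `N > 1` each observation contributes one per-structure error for every
#' structure in the block. Fully reproducible: per-rate seeds are derived
#' deterministically from the master `seed`.
#'
#' @param prior a [ShapePrior-class].
#' @param rates integer vector of rates in bits (strictly increasing).
#' @param nObs observations (blocks) per rate; default 10, the number of
#'   held-out shape observations typically measured per structure.
#' @param N block size (structures coded simultaneously).
#' @param seed master seed.
#' @param nSteps RK4 steps for shooting.
#' @param sizeCap forwarded to [makeCodebook()].
#' @return a [RateErrorCurve-class].
#' @seealso [fitRateAtError()]
#' @export
rateErrorExperiment <- function(prior, rates = seq(0L, 10L, by = 2L),
                                nObs = 10L, N = 1L, seed = 1L,
                                nSteps = 10L, sizeCap = 2^20) {
    stopifnot(is(prior, "ShapePrior"))
    rates <- as.integer(rates)
    if (any(diff(rates) <= 0)) stop("'rates' must be strictly increasing")
    nObs <- as.integer(nObs); N <- as.integer(N)
    B <- length(prior@basis)
    template <- prior@template
    kernel <- prior@kernel

    shootErr <- function(betaSample, betaCode) {
        sA <- shootGeodesic(template, reconstructMomentum(betaSample, prior),
                            kernel, nSteps = nSteps)
        sB <- shootGeodesic(template, reconstructMomentum(betaCode, prior),
                            kernel, nSteps = nSteps)
        hausdorffDistance(sA@deformed, sB@deformed)
    }

    meanE <- numeric(length(rates)); seE <- numeric(length(rates))
    for (k in seq_along(rates)) {
        R <- rates[k]
        cb <- makeCodebook(prior, R, N = N,
                           seed = .stageSeed(seed, 2L * k), sizeCap = sizeCap)
        samp <- samplePrior(prior, nObs * N,
                            seed = .stageSeed(seed, 2L * k + 1L))
        ## rows of `samp` grouped N at a time into blocks
        errs <- numeric(nObs * N)
        for (o in seq_len(nObs)) {
            rows <- ((o - 1L) * N + 1L):(o * N)
            blockBeta <- as.vector(t(samp[rows, , drop = FALSE]))
            code <- decodeCoefficients(encodeCoefficients(blockBeta, cb), cb)
            for (j in seq_len(N)) {
                sl <- ((j - 1L) * B + 1L):(j * B)
                errs[(o - 1L) * N + j] <- shootErr(blockBeta[sl], code[sl])
            }
        }
        meanE[k] <- mean(errs)
        seE[k] <- stats::sd(errs) / sqrt(length(errs))
    }
    new("RateErrorCurve", rateBits = as.numeric(rates), meanErrorMm = meanE,
        stderrMm = seE, nObs = nObs, blockSize = N, seed = as.integer(seed))
}

#' Code rate required at a target geometric accuracy
#'
#' Fits the decreasing curve `err(R) = a * 2^(-b R) + c` (`a, b, c >= 0`)
#' to the per-rate mean errors by bounded Levenberg-Marquardt least
#' squares and solves `err(R) = target` for the rate. The fit is a smooth
#' summary of the measurements, not a generative model. The returned rate
#' is clamped to 0 when the rate-0 (mean-shape) error already meets the
#' target; a target below the fitted floor `c` is an error, since no rate
#' on this curve reaches it. If the exponential fit fails to converge the
#' function falls back to monotone linear interpolation through the
#' measured means, flagged in `fitParams$fallback`.
#'
#' @param curve a [RateErrorCurve-class] with at least 3 rates.
#' @param targetMm geometric error target in mm (e.g. 1.0 or 1.5).
#' @return a [RateAtScale-class].
#' @export
fitRateAtError <- function(curve, targetMm) {
    stopifnot(is(curve, "RateErrorCurve"))
    R <- curve@rateBits; err <- curve@meanErrorMm
    if (length(R) < 3L) stop("need at least 3 rates to fit the curve")
    if (targetMm <= 0) stop("'targetMm' must be > 0")

    fit <- tryCatch({
        cmax <- max(min(err), 1e-12)
        st <- list(a = max(err[1L] - min(err), 1e-6), b = 0.5,
                   c = min(err) * 0.5)
        m <- minpack.lm::nlsLM(err ~ a * 2^(-b * R) + c,
                               data = data.frame(R = R, err = err),
                               start = st,
                               lower = c(a = 0, b = 0, c = 0),
                               control = minpack.lm::nls.lm.control(
                                   maxiter = 500))
        as.list(stats::coef(m))
    }, error = function(e) NULL)

    if (!is.null(fit) && fit$b > 1e-8 && fit$a > 1e-12) {
        params <- c(fit, list(fallback = FALSE))
        err0 <- fit$a + fit$c
        if (err0 <= targetMm || (R[1L] == 0 && err[1L] <= targetMm)) {
            rate <- 0
        } else if (targetMm <= fit$c) {
            stop(sprintf(paste0("target %.3g mm is below the fitted error ",
                                "floor %.3g mm: unreachable at any rate on ",
                                "this curve"), targetMm, fit$c))
        } else {
            rate <- -log2((targetMm - fit$c) / fit$a) / fit$b
            rate <- max(rate, 0)
        }
        return(new("RateAtScale", targetMm = targetMm, rateBits = rate,
                   fitParams = params))
    }

    ## fallback: monotone linear interpolation through the measured means
    errMono <- rev(cummin(rev(err)))   # enforce non-increasing
    errMono <- cummin(errMono)
    if (err[1L] <= targetMm || errMono[1L] <= targetMm) {
        rate <- 0
    } else if (targetMm < min(errMono)) {
        stop(sprintf(paste0("target %.3g mm is below every measured error: ",
                            "unreachable at any rate on this curve"),
                     targetMm))
    } else {
        rate <- stats::approx(errMono, R, xout = targetMm, ties = "ordered",
                              rule = 2L)$y
    }
    new("RateAtScale", targetMm = targetMm, rateBits = rate,
        fitParams = list(fallback = TRUE))
}

#' Storage cost of conventional shape representations
#'
#' Bit counts of the two standard uncompressed representations a discrete
#' shape code is compared against: a binary voxel segmentation mask and a
#' triangulated surface with double-precision coordinates. A typical
#' subcortical mask spans roughly `100^3` voxels (~10^6 bits) and a
#' ~1000-vertex surface costs `1000 * 3 * 64 = 192,000` bits, against
#' which a 32-bit shape code is a compression of four orders of magnitude.
#'
#' @param nVertices vertex count of the surface (default 1000).
#' @param bitsPerScalar bits per stored coordinate (default 64, doubles).
#' @return bits as a numeric scalar.
#' @export
surfaceStorageBits <- function(nVertices = 1000, bitsPerScalar = 64) {
    nVertices * 3 * bitsPerScalar
}

#' @rdname surfaceStorageBits
#' @param voxelsPerSide cube side of the segmentation volume (default 100).
#' @param bitsPerVoxel bits per voxel (default 1, a binary mask).
#' @export
maskStorageBits <- function(voxelsPerSide = 100, bitsPerVoxel = 1) {
    voxelsPerSide^3 * bitsPerVoxel
}
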