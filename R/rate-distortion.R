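#' @include AllClasses.R accessors.R prior.R
NULL

#' Rate-distortion function of a single Gaussian
#'
#' For a Gaussian source of variance `sigma^2` under squared-error
#' distortion, the minimal achievable rate is `R(D) = 1/2 log2(sigma^2/D)`
#' for `0 < D <= sigma^2` and 0 otherwise: when the allowed distortion
#' exceeds the variance a single codeword (the mean) suffices.
#'
#' @param D target distortion (> 0).
#' @param sigma2 source variance (>= 0).
#' @return rate in bits (>= 0).
#' @examples
#' rdRateSingle(1, 4)    # 1 bit
#' rdRateSingle(8, 4)    # 0 bits: distortion above the variance
#' @export
rdRateSingle <- function(D, sigma2) {
    if (D <= 0) stop("'D' must be > 0")
    if (sigma2 < 0) stop("'sigma2' must be >= 0")
    if (D >= sigma2) 0 else 0.5 * log2(sigma2 / D)
}

.waterfillRate <- function(variances, lambda) {
    Di <- pmin(lambda, variances)
    pos <- variances > Di
    sum(0.5 * log2(variances[pos] / Di[pos]))
}

.newWaterfill <- function(variances, lambda) {
    Di <- pmin(lambda, variances)
    new("WaterfillSolution", lambda = lambda, perDimDistortion = Di,
        rateBits = .waterfillRate(variances, lambda),
        totalDistortion = sum(Di))
}

#' Reverse water-filling for independent Gaussians
#'
#' Finds the water level `lambda` such that the per-dimension distortions
#' `D_i = min(lambda, sigma_i^2)` sum to the total budget `D`: dimensions
#' with variance above the water line each absorb `lambda` of distortion,
#' smaller dimensions are fully submerged (coded with zero bits). `lambda`
#' is located by bisection on `[0, max sigma_i^2]` to relative tolerance
#' `1e-12`.
#'
#' If `D` exceeds the total variance, the solution is clamped to the
#' zero-rate regime (`lambda = max sigma_i^2`, `D_i = sigma_i^2`) with a
#' message, matching `R(D) = 0` there.
#'
#' @param variances numeric vector of non-negative source variances.
#' @param D total distortion budget (> 0).
#' @return a [WaterfillSolution-class].
#' @examples
#' reverseWaterfill(c(4, 1), 2)   # lambda = 1, rate = 1 bit
#' @export
reverseWaterfill <- function(variances, D) {
    if (D <= 0) stop("'D' must be > 0")
    if (any(variances < 0)) stop("variances must be non-negative")
    total <- sum(variances)
    if (D >= total) {
        if (D > total)
            message(sprintf(
                "distortion %g exceeds total variance %g; clamped to rate 0",
                D, total))
        return(.newWaterfill(variances, max(variances)))
    }
    lo <- 0; hi <- max(variances)
    for (it in seq_len(200L)) {
        mid <- (lo + hi) / 2
        if (sum(pmin(mid, variances)) < D) lo <- mid else hi <- mid
        if ((hi - lo) <= 1e-14 * max(hi, 1)) break
    }
    lambda <- (lo + hi) / 2
    ## bisection leaves a tiny residual in sum(D_i) = D; close it exactly
    ## by adjusting lambda over the dims still above the water line
    above <- variances > lambda
    if (any(above))
        lambda <- (D - sum(variances[!above])) / sum(above)
    .newWaterfill(variances, lambda)
}

#' Rate-distortion function of independent Gaussians
#'
#' Evaluates `R(D) = sum_i 1/2 log2(sigma_i^2 / D_i)` with the `D_i` from
#' reverse water-filling; the minimal rate achievable at total squared
#' error `D`, approached asymptotically by random block codes.
#'
#' @inheritParams reverseWaterfill
#' @return rate in bits (>= 0).
#' @export
rateOfDistortion <- function(variances, D) {
    reverseWaterfill(variances, D)@rateBits
}

#' Water level achieving a target rate
#'
#' Inverts the Gaussian rate-distortion function: finds `lambda` (hence
#' the distortion allocation) at which the water-filled rate equals `R`
#' bits, by bisection on the water level to `1e-9` bits. Every `R >= 0` is
#' achievable; `R = 0` returns `lambda = max sigma_i^2` (the all-zero
#' codeword regime).
#'
#' @param variances numeric vector of non-negative source variances.
#' @param R target rate in bits (>= 0).
#' @return a [WaterfillSolution-class] with `rateBits` equal to `R` within
#'   `1e-9`.
#' @examples
#' lambdaForRate(c(4, 1), 1)   # lambda = 1, total distortion 2
#' @export
lambdaForRate <- function(variances, R) {
    if (R < 0) stop("'R' must be >= 0")
    if (any(variances < 0)) stop("variances must be non-negative")
    vmax <- max(variances)
    if (R == 0 || vmax == 0) return(.newWaterfill(variances, vmax))
    ## rate(lambda) decreases continuously from +Inf (lambda -> 0) to 0
    ## (lambda = vmax); bracket below using rate >= 1/2 log2(vmax/lambda)
    lo <- vmax * 2^(-2 * (R + 1)); hi <- vmax
    mid <- sqrt(lo * hi)
    for (it in seq_len(300L)) {
        mid <- sqrt(lo * hi)
        r <- .waterfillRate(variances, mid)
        if (abs(r - R) <= 1e-12) break
        if (r > R) lo <- mid else hi <- mid
    }
    .newWaterfill(variances, mid)
}

#' Build a random rate-distortion codebook
#'
#' Constructs the `2^(N*R)`-codeword random Gaussian code for a shape
#' prior at rate `R` bits per structure and block size `N` (coding `N`
#' independent instances of the structure simultaneously). The water level
#' comes from [lambdaForRate()] on the `N`-fold replicated spectrum at
#' total rate `N*R` (by symmetry this equals the single-structure level).
#' Codeword component `i` is drawn `N(0, sigma_i^2 - lambda)` when
#' `sigma_i^2 >= lambda` and is exactly 0 otherwise; draws are
#' reproducible from `seed`.
#'
#' @param prior a [ShapePrior-class], or a numeric vector of variances.
#' @param R integer rate per structure, in bits (>= 0).
#' @param N block size (>= 1).
#' @param seed RNG seed stored in the codebook.
#' @param sizeCap refuse to build codebooks larger than this many
#'   codewords (default `2^20`); raise explicitly for larger searches.
#' @return a [Codebook-class].
#' @export
makeCodebook <- function(prior, R, N = 1L, seed = 1L, sizeCap = 2^20) {
    vars <- if (is(prior, "ShapePrior")) prior@variances else
        as.numeric(prior)
    priorId <- if (is(prior, "ShapePrior"))
        sprintf("ShapePrior/%d-modes", length(vars)) else "variances"
    R <- as.integer(R); N <- as.integer(N)
    if (R < 0) stop("'R' must be >= 0")
    if (N < 1L) stop("'N' must be >= 1")
    size <- 2^(as.numeric(N) * R)
    if (size > sizeCap)
        stop(sprintf(paste0("codebook size 2^(%d*%d) = %.3g exceeds the cap ",
                            "%.3g; lower R or raise 'sizeCap'"),
                     N, R, size, sizeCap))
    wf <- lambdaForRate(rep(vars, N), N * R)
    lambda <- wf@lambda
    B <- length(vars)
    sds <- sqrt(pmax(rep(vars, N) - lambda, 0))
    sds[rep(vars, N) < lambda] <- 0
    cw <- .withSeed(seed, {
        z <- matrix(stats::rnorm(size * N * B), nrow = size, byrow = TRUE)
        sweep(z, 2L, sds, `*`)
    })
    cw[, sds == 0] <- 0
    new("Codebook", rateBits = R, blockSize = N, lambda = lambda,
        codewords = cw, variances = vars, seed = as.integer(seed),
        priorId = priorId)
}

#' Encode coefficients to the nearest codeword
#'
#' Maps a coefficient vector (the concatenated coefficients of the `N`
#' structures in a block) to the index of the codeword minimizing squared
#' Euclidean distance; ties break to the lowest index. Indices are 0-based:
#' the index is the value of the length-`N*R` binary string naming the
#' codeword.
#'
#' @param beta numeric vector of length `N*B`, or a matrix with one such
#'   vector per row.
#' @param codebook a [Codebook-class].
#' @return integer index (0-based), or a vector of them for matrix input.
#' @export
encodeCoefficients <- function(beta, codebook) {
    single <- is.null(dim(beta))
    if (single) beta <- matrix(beta, nrow = 1L)
    C <- codebook@codewords
    if (ncol(beta) != ncol(C))
        stop(sprintf("coefficient dimension %d does not match codeword dimension %d",
                     ncol(beta), ncol(C)))
    cn <- rowSums(C^2)
    idx <- integer(nrow(beta))
    chunk <- max(1L, floor(4e6 / max(1L, nrow(C))))
    for (s in seq(1L, nrow(beta), by = chunk)) {
        e <- min(s + chunk - 1L, nrow(beta))
        ## dist^2 = |c|^2 - 2 c.b (+ |b|^2, constant per row)
        D <- matrix(cn, e - s + 1L, nrow(C), byrow = TRUE) -
            2 * tcrossprod(beta[s:e, , drop = FALSE], C)
        idx[s:e] <- max.col(-D, ties.method = "first") - 1L
    }
    if (single) idx[1L] else idx
}

#' Decode a codeword index
#'
#' @param index 0-based codeword index (vectorized).
#' @param codebook a [Codebook-class].
#' @return the stored codeword (numeric vector), or a matrix of codewords
#'   for vector input.
#' @export
decodeCoefficients <- function(index, codebook) {
    size <- nrow(codebook@codewords)
    if (any(index < 0L) || any(index >= size))
        stop(sprintf("codeword index out of range [0, %d)", size))
    out <- codebook@codewords[index + 1L, , drop = FALSE]
    if (length(index) == 1L) as.numeric(out) else out
}

#' Empirical squared-error distortion of a codebook
#'
#' Mean over samples of the squared Euclidean distance between a
#' coefficient vector and its decoded nearest codeword, divided by the
#' block size `N` (per-structure normalization, so `N = 1` and `N = 2`
#' curves are directly comparable).
#'
#' @param samples numeric matrix, one length-`N*B` coefficient vector per
#'   row.
#' @param codebook a [Codebook-class].
#' @param detail if TRUE, return a list with the per-sample distortions
#'   and the standard error of the mean.
#' @return numeric(1) mean distortion per structure, or a list when
#'   `detail = TRUE`.
#' @export
empiricalDistortion <- function(samples, codebook, detail = FALSE) {
    if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
    if (nrow(samples) < 1L) stop("need at least one sample")
    idx <- encodeCoefficients(samples, codebook)
    rec <- codebook@codewords[idx + 1L, , drop = FALSE]
    d <- rowSums((samples - rec)^2) / codebook@blockSize
    if (!detail) return(mean(d))
    list(mean = mean(d), stderr = stats::sd(d) / sqrt(length(d)),
         perSample = d)
}
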