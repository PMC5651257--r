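#' @include AllClasses.R accessors.R
NULL

#' Gaussian kernel weight for a displacement
#'
#' Evaluates the unnormalized Gaussian `K(dx) = exp(-|dx|^2 / (2 sigma^2))`
#' used both as the velocity-field kernel and as the metric kernel of the
#' momentum inner product. `K(0) = 1` by construction.
#'
#' @param dx a 3-vector displacement in mm, or a matrix with one
#'   displacement per row.
#' @param kernel a [KernelSpec-class] (default sigma = 6.5 mm).
#' @return numeric weight(s) in (0, 1].
#' @examples
#' gaussKernel(c(0, 0, 0))              # 1
#' gaussKernel(c(6.5, 0, 0))            # exp(-1/2)
#' @export
gaussKernel <- function(dx, kernel = kernelSpec()) {
    if (is.null(dim(dx))) dx <- matrix(dx, ncol = 3L)
    stopifnot(all(is.finite(dx)))
    w <- exp(-rowSums(dx^2) / (2 * kernel@sigma^2))
    if (length(w) == 1L) as.numeric(w) else w
}

#' Kernel-weighted velocity field
#'
#' The velocity induced by momenta `p_i` at particle positions `x_i` is
#' `v(x) = sum_i K(x - x_i) p_i`. This is the right-hand side of the
#' particle flow and the field a template vertex moves with during
#' geodesic shooting.
#'
#' @param x query point (3-vector) or matrix of query points (rows).
#' @param points numeric matrix `n x 3` of particle positions.
#' @param mom numeric matrix `n x 3` of particle momenta.
#' @param kernel a [KernelSpec-class].
#' @return a 3-vector (single query) or matrix of velocities.
#' @export
velocityField <- function(x, points, mom, kernel = kernelSpec()) {
    single <- is.null(dim(x))
    if (single) x <- matrix(x, ncol = 3L)
    points <- as.matrix(points); mom <- as.matrix(mom)
    if (nrow(points) != nrow(mom))
        stop("'points' and 'mom' must have the same number of rows")
    v <- .kernelMatrix(x, points, kernel@sigma) %*% mom
    if (single) as.numeric(v) else v
}

## One evaluation of the Hamiltonian particle system:
##   xdot_i = sum_j K_ij p_j
##   pdot_i = sum_j (p_i . p_j) K_ij (x_i - x_j) / sigma^2
## (pdot = -Dv(x_i)^T p_i with the Gaussian kernel gradient
##  grad K(dx) = -(dx / sigma^2) K(dx) evaluated analytically).
.shootDeriv <- function(X, P, sigma) {
    K <- .kernelMatrix(X, X, sigma)
    M <- K * tcrossprod(P) / sigma^2
    list(xdot = K %*% P,
         pdot = rowSums(M) * X - M %*% X)
}

.hamiltonian <- function(X, P, sigma) {
    0.5 * sum(P * (.kernelMatrix(X, X, sigma) %*% P))
}

#' Geodesic shooting of a template from initial momenta
#'
#' Integrates the Hamiltonian particle system
#' `xdot_i = v(x_i)`, `pdot_i = -Dv(x_i)^T p_i` over `t` in `[0, 1]` with
#' fixed-step fourth-order Runge-Kutta, carrying the template vertices
#' along the diffeomorphic flow generated by the initial momentum. The
#' Jacobian `Dv` is evaluated analytically from the Gaussian kernel
#' gradient. The Hamiltonian `H = 1/2 sum_ij p_i' K(x_i - x_j) p_j` is
#' conserved along exact geodesics; its recorded trace is a built-in
#' accuracy diagnostic.
#'
#' @param template a [TriSurface-class]; its vertices are the particles.
#' @param p0 a [MomentumField-class] matching the template vertex count.
#' @param kernel a [KernelSpec-class].
#' @param nSteps number of RK4 steps over `[0, 1]` (default 10).
#' @param storeTrajectory if TRUE, keep per-step positions and momenta.
#' @return a [ShootingResult-class]; `deformed(x)` is the template carried
#'   to `t = 1` with its face list intact.
#' @examples
#' surf <- makeTemplate(syntheticSpec(subdivisions = 1L))
#' p0 <- momentumField(matrix(0, nVertices(surf), 3))
#' res <- shootGeodesic(surf, p0)
#' identical(vertices(deformed(res)), vertices(surf))  # identity flow
#' @export
shootGeodesic <- function(template, p0, kernel = kernelSpec(),
                          nSteps = 10L, storeTrajectory = FALSE) {
    stopifnot(is(template, "TriSurface"), is(p0, "MomentumField"))
    if (nVertices(p0) != nVertices(template))
        stop(sprintf("momentum field has %d vertices but template has %d",
                     nVertices(p0), nVertices(template)))
    nSteps <- as.integer(nSteps)
    if (nSteps < 1L) stop("'nSteps' must be >= 1")
    sigma <- kernel@sigma
    X <- template@vertices
    P <- p0@values
    h <- 1 / nSteps
    H <- numeric(nSteps + 1L)
    H[1L] <- .hamiltonian(X, P, sigma)
    traj <- if (storeTrajectory) vector("list", nSteps + 1L) else NULL
    if (storeTrajectory) traj[[1L]] <- list(x = X, p = P)

    for (step in seq_len(nSteps)) {
        k1 <- .shootDeriv(X, P, sigma)
        k2 <- .shootDeriv(X + h / 2 * k1$xdot, P + h / 2 * k1$pdot, sigma)
        k3 <- .shootDeriv(X + h / 2 * k2$xdot, P + h / 2 * k2$pdot, sigma)
        k4 <- .shootDeriv(X + h * k3$xdot, P + h * k3$pdot, sigma)
        X <- X + h / 6 * (k1$xdot + 2 * k2$xdot + 2 * k3$xdot + k4$xdot)
        P <- P + h / 6 * (k1$pdot + 2 * k2$pdot + 2 * k3$pdot + k4$pdot)
        if (!all(is.finite(X)) || !all(is.finite(P)))
            stop(sprintf(paste0("non-finite state at RK4 step %d of %d; ",
                                "momenta too large for this step count"),
                         step, nSteps))
        H[step + 1L] <- .hamiltonian(X, P, sigma)
        if (storeTrajectory) traj[[step + 1L]] <- list(x = X, p = P)
    }

    new("ShootingResult",
        deformed = new("TriSurface", vertices = X, faces = template@faces),
        trajectory = traj, hamiltonianTrace = H)
}
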