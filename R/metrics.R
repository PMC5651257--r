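#' @include AllClasses.R accessors.R
NULL

#' Hausdorff distance between two surfaces
#'
#' Symmetric vertex-set Hausdorff distance in mm:
#' `max( max_a min_b |v_a - w_b|, max_b min_a |v_a - w_b| )`.
#' Face lists are ignored; the comparison is between vertex point sets and
#' is correspondence-free (closest pairs, not index-matched). This is the
#' sup-norm boundary error an anatomist would read off two overlaid
#' structures.
#'
#' The index-matched variant (`type = "corresponding"`), the maximum
#' distance between same-index vertices, is exposed for meshes in known
#' correspondence but is not used by any default pipeline.
#'
#' @param A,B [TriSurface-class] objects (or `n x 3` vertex matrices).
#' @param type `"hausdorff"` (default) or `"corresponding"`.
#' @return distance in mm.
#' @examples
#' s <- makeTemplate(syntheticSpec(subdivisions = 0L))
#' t <- triSurface(vertices(s) + rep(c(1, 0, 0), each = nVertices(s)),
#'                 faces(s))
#' hausdorffDistance(s, t)   # 1 mm rigid translation
#' @export
hausdorffDistance <- function(A, B, type = c("hausdorff", "corresponding")) {
    type <- match.arg(type)
    VA <- if (is(A, "TriSurface")) A@vertices else as.matrix(A)
    VB <- if (is(B, "TriSurface")) B@vertices else as.matrix(B)
    if (nrow(VA) < 1L || nrow(VB) < 1L)
        stop("both surfaces must have at least one vertex")
    if (type == "corresponding") {
        if (nrow(VA) != nrow(VB))
            stop("index-matched distance requires equal vertex counts")
        return(sqrt(max(rowSums((VA - VB)^2))))
    }
    ## chunk the pairwise distance matrix to bound memory on large meshes
    chunk <- max(1L, floor(4e6 / nrow(VB)))
    dAB <- 0; dBAmin <- rep(Inf, nrow(VB))
    for (s in seq(1L, nrow(VA), by = chunk)) {
        e <- min(s + chunk - 1L, nrow(VA))
        d2 <- .pairdist2exact(VA[s:e, , drop = FALSE], VB)
        dAB <- max(dAB, max(apply(d2, 1L, min)))
        dBAmin <- pmin(dBAmin, apply(d2, 2L, min))
    }
    sqrt(max(dAB, max(dBAmin)))
}
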