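#' @include AllClasses.R
NULL

#' Extract vertex coordinates
#'
#' @param x an object with vertices (e.g. [TriSurface-class]).
#' @return numeric matrix `n x 3` (mm).
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' Extract the triangle index list
#'
#' @param x a [TriSurface-class].
#' @return integer matrix `m x 3` of 0-based vertex indices.
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' Number of vertices
#'
#' @param x a [TriSurface-class] or [MomentumField-class].
#' @return integer(1).
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' Extract momentum vectors
#'
#' @param x a [MomentumField-class] (or an object holding one).
#' @return numeric matrix `n x 3`.
#' @export
setGeneric("momenta", function(x) standardGeneric("momenta"))

#' Kernel standard deviation in mm
#'
#' @param x a [KernelSpec-class] or an object carrying one.
#' @return numeric(1).
#' @export
setGeneric("kernelSigma", function(x) standardGeneric("kernelSigma"))

#' Per-mode variances of a shape model
#'
#' @param x a [ShapePrior-class], [Codebook-class] or [WaterfillSolution-class].
#' @return numeric vector.
#' @export
setGeneric("variances", function(x) standardGeneric("variances"))

#' Number of retained modes / coefficient dimension
#'
#' @param x a [ShapePrior-class].
#' @return integer(1).
#' @export
setGeneric("nModes", function(x) standardGeneric("nModes"))

#' Code rate in bits
#'
#' @param x a [Codebook-class], [WaterfillSolution-class],
#'   [RateErrorCurve-class] or [RateAtScale-class].
#' @return numeric; for curves, the rate grid.
#' @export
setGeneric("rateBits", function(x) standardGeneric("rateBits"))

#' Number of codewords
#'
#' @param x a [Codebook-class].
#' @return numeric(1), `2^(N*R)`.
#' @export
setGeneric("codebookSize", function(x) standardGeneric("codebookSize"))
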