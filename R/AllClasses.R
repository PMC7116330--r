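#' @import methods
NULL

.SYM_TOL <- 1e-10

#' Symmetric non-negative affinity (weighted adjacency) matrix
#'
#' An \code{AffinityMatrix} is a square numeric matrix of pairwise similarity
#' weights between graph nodes (voxels, surface vertices or pixels).  It must
#' be symmetric within \code{1e-10}, non-negative, with a zero diagonal:
#' self-similarity is always maximal and carries no information, and keeping
#' self-loops out of the degree makes the all-ones-affinity ceiling of the
#' Vogt-Bailey index exact.  The \code{dropped} slot records the original
#' indices of nodes removed upstream (degenerate features, isolated nodes) so
#' results can be re-expanded to the full node set.
#'
#' @slot .Data the \code{n x n} weight matrix.
#' @slot dropped integer vector of original node indices excluded when the
#'   matrix was built (empty when none were).
#'
#' @seealso [affinityMatrix()], [buildAffinity()], [degreeMatrix()]
#' @export
setClass("AffinityMatrix",
  contains = "matrix",
  representation(dropped = "integer"),
  prototype(dropped = integer(0))
)

setValidity("AffinityMatrix", function(object) {
  w <- object@.Data
  if (!is.numeric(w) || length(dim(w)) != 2L || nrow(w) != ncol(w))
    return("weights must be a square numeric matrix")
  if (any(!is.finite(w)))
    return("weights must be finite")
  if (max(abs(w - t(w))) > .SYM_TOL)
    return(sprintf("matrix is asymmetric beyond tolerance %g", .SYM_TOL))
  if (any(w < 0))
    return("affinity weights must be non-negative")
  if (any(diag(w) != 0))
    return("diagonal must be zero (self-loops are excluded)")
  TRUE
})

#' Construct an AffinityMatrix
#'
#' Validates a square numeric matrix as an affinity matrix.  Asymmetric input
#' (beyond \code{1e-10}) is rejected rather than silently symmetrised:
#' asymmetry indicates a bug upstream.  The diagonal must already be zero;
#' use \code{zeroDiagonal = TRUE} to clear an all-but-diagonal-valid matrix.
#'
#' @param weights square numeric matrix of non-negative weights.
#' @param zeroDiagonal if \code{TRUE}, the diagonal is set to zero before
#'   validation (self-similarities from a pairwise metric are discarded).
#' @param dropped integer vector of original node indices this matrix no
#'   longer contains.
#' @return an [AffinityMatrix-class] object.
#' @examples
#' W <- matrix(c(0, .4, .4, 0), 2, 2)
#' affinityMatrix(W)
#' @export
affinityMatrix <- function(weights, zeroDiagonal = FALSE, dropped = integer(0)) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (zeroDiagonal && nrow(weights) == ncol(weights)) diag(weights) <- 0
  new("AffinityMatrix", weights, dropped = as.integer(dropped))
}

#' Graph Laplacian in one of three variants
#'
#' Holds the Laplacian matrix of a weighted graph together with the degree
#' vector it was built from.  Variants: \code{"unnormalized"} (\eqn{L = D - W}),
#' \code{"symmetric"} (\eqn{D^{-1/2} L D^{-1/2}}) and \code{"random_walk"}
#' (\eqn{D^{-1} L}).
#'
#' @slot matrix the \code{n x n} Laplacian matrix.
#' @slot variant one of \code{"unnormalized"}, \code{"symmetric"},
#'   \code{"random_walk"}.
#' @slot degrees the node degree vector (row sums of the affinity matrix).
#' @slot dropped original indices of isolated nodes removed under the
#'   \code{"drop"} policy (empty otherwise).
#' @seealso [laplacianMatrix()]
#' @export
setClass("Laplacian",
  representation(matrix = "matrix", variant = "character",
                 degrees = "numeric", dropped = "integer"),
  prototype(dropped = integer(0))
)

setValidity("Laplacian", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("Laplacian must be square")
  if (length(object@degrees) != nrow(m))
    return("degrees length must match matrix dimension")
  if (!object@variant %in% c("unnormalized", "symmetric", "random_walk"))
    return("unknown Laplacian variant")
  if (object@variant %in% c("unnormalized", "random_walk")) {
    if (max(abs(rowSums(m))) > 1e-8)
      return("Laplacian rows must sum to zero")
  }
  TRUE
})

#' Policy for turning feature similarity into a non-negative affinity
#'
#' Bundles the similarity metric with the non-negativity strategy and optional
#' sparsification.  The default recipe (Pearson correlation, negative
#' correlations clamped to zero, retained values mapped through the angular
#' similarity transform) yields weights in \eqn{[0, 1]} without any shift
#' constant.
#'
#' @slot metric one of \code{"dot"}, \code{"cosine"}, \code{"pearson"},
#'   \code{"ang_sim"}.
#' @slot negativity one of \code{"zero_negatives"} (clamp negatives to 0),
#'   \code{"shift_constant"} (add \code{shift}), \code{"none"}.
#' @slot shift non-negative scalar added under \code{"shift_constant"}.
#' @slot thresholdEps numeric; weights below it are zeroed (\code{NA} = off).
#' @slot knnK integer; keep each node's k strongest weights, symmetrised by
#'   union (\code{NA} = off).  Mutually exclusive with \code{thresholdEps}.
#' @slot binarize logical; retained nonzero weights become 1.
#' @seealso [affinityPolicy()], [buildAffinity()]
#' @export
setClass("AffinityPolicy",
  representation(metric = "character", negativity = "character",
                 shift = "numeric", thresholdEps = "numeric",
                 knnK = "integer", binarize = "logical")
)

setValidity("AffinityPolicy", function(object) {
  if (!object@metric %in% c("dot", "cosine", "pearson", "ang_sim"))
    return("unknown metric")
  if (!object@negativity %in% c("zero_negatives", "shift_constant", "none"))
    return("unknown negativity policy")
  if (length(object@shift) != 1L || is.na(object@shift) || object@shift < 0)
    return("shift must be a single non-negative number")
  if (!is.na(object@thresholdEps) && !is.na(object@knnK))
    return("thresholdEps and knnK are mutually exclusive")
  if (!is.na(object@knnK) && object@knnK < 1L)
    return("knnK must be a positive integer")
  TRUE
})

#' @rdname AffinityPolicy-class
#' @param metric,negativity,shift,thresholdEps,knnK,binarize see slots.
#' @return an \code{AffinityPolicy} object.
#' @examples
#' affinityPolicy()                       # default: pearson -> clamp -> AngSim
#' affinityPolicy("pearson", knnK = 6)    # sparse k-NN graph
#' @export
affinityPolicy <- function(metric = c("ang_sim", "pearson", "cosine", "dot"),
                           negativity = c("zero_negatives", "shift_constant",
                                          "none"),
                           shift = 0, thresholdEps = NA_real_,
                           knnK = NA_integer_, binarize = FALSE) {
  new("AffinityPolicy",
      metric = match.arg(metric), negativity = match.arg(negativity),
      shift = as.numeric(shift), thresholdEps = as.numeric(thresholdEps),
      knnK = as.integer(knnK), binarize = isTRUE(binarize))
}

#' Eigendecomposition of a graph Laplacian problem
#'
#' Full ascending eigendecomposition of one of the four Laplacian eigenvalue
#' problems: \code{"standard"} (\eqn{Lx = \lambda x}), \code{"generalized"}
#' (\eqn{Lx = \lambda Dx}, eigenvectors normalised so \eqn{x^T D x = 1}),
#' \code{"symmetric_normalized"} and \code{"random_walk"}.  Eigenvector signs
#' follow a fixed convention (largest-magnitude component positive) so maps
#' are reproducible and not merely defined up to reflection.
#'
#' @slot values eigenvalues, sorted ascending.
#' @slot vectors matrix with column \code{i} paired to \code{values[i]}.
#' @slot problem which eigenproblem was solved.
#' @slot degenerate \code{TRUE} when the Fiedler value is (numerically)
#'   repeated, in which case the Fiedler vector is one member of an arbitrary
#'   basis.
#' @seealso [solveEigenproblem()], [fiedlerPair()]
#' @export
setClass("EigenSolution",
  representation(values = "numeric", vectors = "matrix",
                 problem = "character", degenerate = "logical")
)

setValidity("EigenSolution", function(object) {
  if (is.unsorted(object@values, strictly = FALSE))
    return("eigenvalues must be sorted ascending")
  if (ncol(object@vectors) != length(object@values))
    return("one eigenvector column per eigenvalue required")
  if (!object@problem %in% c("standard", "generalized",
                             "symmetric_normalized", "random_walk"))
    return("unknown eigenproblem")
  TRUE
})

#' Low-dimensional spectral embedding of graph nodes
#'
#' Embedding coordinates taken from eigenvectors 2..d+1 of a Laplacian
#' eigenproblem, together with the spectral reordering (rank order along the
#' Fiedler vector) and, when at least three dimensions are requested, an RGB
#' colour encoding with each channel min-max scaled to \eqn{[0, 1]}.
#'
#' @slot coords \code{n x d} embedding coordinates.
#' @slot ranks integer permutation of \code{1..n}: rank along dimension 1.
#' @slot rgb \code{n x 3} matrix in \eqn{[0,1]}, or a 0-row matrix when
#'   fewer than 3 dimensions were requested.
#' @seealso [gradientMap()], [spectralReorder()], [rgbMap()]
#' @export
setClass("GradientMap",
  representation(coords = "matrix", ranks = "integer", rgb = "matrix")
)

setValidity("GradientMap", function(object) {
  n <- nrow(object@coords)
  if (length(object@ranks) != n) return("one rank per node required")
  if (n && !setequal(object@ranks, seq_len(n)))
    return("ranks must be a permutation of 1..n")
  if (nrow(object@rgb) && (nrow(object@rgb) != n || ncol(object@rgb) != 3L))
    return("rgb must be n x 3")
  if (nrow(object@rgb) &&
      (min(object@rgb) < -1e-12 || max(object@rgb) > 1 + 1e-12))
    return("rgb values must lie in [0,1]")
  TRUE
})

#' Result of a Vogt-Bailey analysis
#'
#' @slot mode \code{"full"}, \code{"clustered"} or \code{"searchlight"}.
#' @slot vb the VB index values: a scalar (full), a vector named by cluster id
#'   (clustered), or a per-vertex vector with \code{NA} at vertices where the
#'   index is undefined (searchlight).
#' @slot gradient a [GradientMap-class] (full), a named list of them
#'   (clustered), or \code{NULL} (searchlight).
#' @slot problem the eigenproblem used.
#' @slot neighborhoodSizes searchlight only: number of vertices in each
#'   neighbourhood (0 where unmasked).
#' @seealso [vbIndex()], [fullAnalysis()], [clusteredAnalysis()],
#'   [searchlightAnalysis()]
#' @export
setClass("VBResult",
  representation(mode = "character", vb = "numeric", gradient = "ANY",
                 problem = "character", neighborhoodSizes = "integer")
)

setValidity("VBResult", function(object) {
  if (!object@mode %in% c("full", "clustered", "searchlight"))
    return("unknown analysis mode")
  v <- object@vb[!is.na(object@vb)]
  if (length(v) && (min(v) < -1e-8 || max(v) > 1 + 1e-8))
    return("VB values must lie in [0,1] (within 1e-8)")
  TRUE
})

#' Triangulated surface mesh
#'
#' Vertex coordinates in millimetres plus a triangle index list.  Triangle
#' indices are 1-based inside the package (the R convention); GIFTI's 0-based
#' indices are converted at the I/O boundary.  Vertices referenced by no
#' triangle are permitted (orphans) but have no one-ring neighbourhood and are
#' excluded as searchlight centres.
#'
#' @slot vertices \code{n x 3} numeric coordinates.
#' @slot triangles \code{m x 3} integer matrix of 1-based vertex indices.
#' @seealso [surfaceMesh()], [oneRing()], [makeIcosphere()]
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix")
)

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; tr <- object@triangles
  if (ncol(v) != 3L) return("vertices must be n x 3")
  if (ncol(tr) != 3L) return("triangles must be m x 3")
  if (nrow(tr)) {
    if (min(tr) < 1L || max(tr) > nrow(v))
      return("triangle indices out of range")
    if (any(tr[, 1] == tr[, 2] | tr[, 1] == tr[, 3] | tr[, 2] == tr[, 3]))
      return("degenerate triangle (repeated vertex)")
  }
  TRUE
})

#' Construct a SurfaceMesh
#'
#' @param vertices \code{n x 3} numeric matrix of coordinates.
#' @param triangles \code{m x 3} matrix of 1-based vertex indices.
#' @return a [SurfaceMesh-class] object.
#' @export
surfaceMesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  dimnames(vertices) <- dimnames(triangles) <- NULL
  new("SurfaceMesh", vertices = vertices, triangles = triangles)
}

#' Accessors for mesh geometry
#' @param mesh a [SurfaceMesh-class].
#' @return `meshVertices()` the coordinate matrix; `meshTriangles()` the
#'   triangle index matrix.
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @rdname meshVertices
#' @export
meshTriangles <- function(mesh) mesh@triangles

#' @rdname meshVertices
#' @export
nVertices <- function(mesh) nrow(mesh@vertices)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d triangles\n",
              nrow(object@vertices), nrow(object@triangles)))
})

setMethod("show", "AffinityMatrix", function(object) {
  cat(sprintf("AffinityMatrix: %d nodes, %d nonzero edges%s\n",
              nrow(object), sum(object@.Data[upper.tri(object@.Data)] > 0),
              if (length(object@dropped))
                sprintf(" (%d nodes dropped)", length(object@dropped)) else ""))
})

setMethod("show", "Laplacian", function(object) {
  cat(sprintf("Laplacian (%s): %d nodes\n", object@variant,
              nrow(object@matrix)))
})

setMethod("show", "EigenSolution", function(object) {
  n <- length(object@values)
  cat(sprintf("EigenSolution (%s problem): n = %d\n", object@problem, n))
  cat("  smallest eigenvalues:",
      paste(signif(utils::head(object@values, 4), 4), collapse = ", "), "\n")
  if (object@degenerate)
    cat("  note: Fiedler value is degenerate (repeated eigenvalue)\n")
})

setMethod("show", "GradientMap", function(object) {
  cat(sprintf("GradientMap: %d nodes, %d embedding dimension(s)%s\n",
              nrow(object@coords), ncol(object@coords),
              if (nrow(object@rgb)) ", with RGB encoding" else ""))
})

setMethod("show", "VBResult", function(object) {
  cat(sprintf("VBResult (%s analysis, %s problem)\n",
              object@mode, object@problem))
  v <- object@vb
  if (object@mode == "full") {
    cat(sprintf("  VB index: %.6f\n", v))
  } else {
    cat(sprintf("  %d values, range [%.4f, %.4f], %d missing\n",
                length(v), suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  }
})

#' Accessors for analysis results
#'
#' @param result a [VBResult-class].
#' @return `vbValues()` the VB index value(s); `vbGradient()` the gradient
#'   map(s) or `NULL`; `vbMode()` the analysis mode.
#' @export
vbValues <- function(result) result@vb

#' @rdname vbValues
#' @export
vbGradient <- function(result) result@gradient

#' @rdname vbValues
#' @export
vbMode <- function(result) result@mode

#' Accessors for eigen solutions and gradient maps
#' @param solution an [EigenSolution-class].
#' @return `eigenValues()`/`eigenVectors()` the spectrum;
#'   `gradientCoords()`, `gradientRanks()`, `gradientRGB()` the embedding
#'   pieces of a [GradientMap-class].
#' @export
eigenValues <- function(solution) solution@values

#' @rdname eigenValues
#' @export
eigenVectors <- function(solution) solution@vectors

#' @rdname eigenValues
#' @param map a [GradientMap-class].
#' @export
gradientCoords <- function(map) map@coords

#' @rdname eigenValues
#' @export
gradientRanks <- function(map) map@ranks

#' @rdname eigenValues
#' @export
gradientRGB <- function(map) map@rgb
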