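#' Solve a Laplacian eigenvalue problem
#'
#' Solves one of four eigenproblems for a graph with unnormalized Laplacian
#' \eqn{L = D - W}:
#' \describe{
#'   \item{standard}{\eqn{Lx = \lambda x}, from minimising the embedding cost
#'     \eqn{U(x) = \sum_{ij} W_{ij}(x_i - x_j)^2} under \eqn{x^T x = 1}.}
#'   \item{generalized}{\eqn{Lx = \lambda Dx}, the degree-weighted constraint
#'     \eqn{x^T D x = 1}; compensates the bias towards high-degree nodes and
#'     is the default throughout the package.}
#'   \item{symmetric_normalized}{the standard problem of
#'     \eqn{D^{-1/2} L D^{-1/2}}.}
#'   \item{random_walk}{the eigenproblem of \eqn{D^{-1} L}; its eigenvalues
#'     equal the generalized ones.}
#' }
#' All four are reduced to a dense symmetric eigendecomposition: the three
#' degree-normalised problems are solved on the symmetric normalized form and
#' back-transformed, which is numerically stable whenever all degrees are
#' strictly positive.  Eigenvalues are returned ascending; each eigenvector's
#' sign is fixed so its largest-magnitude component is positive (first such
#' component on ties).
#'
#' @param laplacian an unnormalized [Laplacian-class] (from
#'   [laplacianMatrix()]), or an [AffinityMatrix-class]/plain affinity matrix
#'   from which it is built.
#' @param problem which eigenproblem to solve.
#' @return an [EigenSolution-class]; its \code{degenerate} flag is set when
#'   the second eigenvalue is numerically repeated, in which case gradients
#'   are only defined up to rotation within the eigenspace.
#' @examples
#' es <- solveEigenproblem(toyGraphs()$fig1, "standard")
#' round(eigenValues(es), 8)   # 0 1 3 4
#' @export
solveEigenproblem <- function(laplacian,
                              problem = c("generalized", "standard",
                                          "symmetric_normalized",
                                          "random_walk")) {
  problem <- match.arg(problem)
  if (!is(laplacian, "Laplacian"))
    laplacian <- laplacianMatrix(laplacian, "unnormalized")
  if (laplacian@variant != "unnormalized")
    stop("solveEigenproblem() transforms the unnormalized Laplacian itself; ",
         "pass variant = \"unnormalized\"")
  L <- laplacian@matrix
  d <- laplacian@degrees
  n <- nrow(L)

  if (problem == "standard") {
    eg <- eigen(L, symmetric = TRUE)
    vals <- rev(eg$values)
    vecs <- eg$vectors[, rev(seq_len(n)), drop = FALSE]
  } else {
    if (any(d <= 0))
      stop("degenerate degree: normalized/generalized problems need all ",
           "degrees > 0 (isolated nodes: ",
           paste(which(d <= 0), collapse = ", "), ")")
    s <- 1 / sqrt(d)
    Lsym <- L * (s %o% s)
    Lsym <- (Lsym + t(Lsym)) / 2
    eg <- eigen(Lsym, symmetric = TRUE)
    vals <- rev(eg$values)
    Y <- eg$vectors[, rev(seq_len(n)), drop = FALSE]
    vecs <- switch(problem,
      symmetric_normalized = Y,
      # x = D^{-1/2} y keeps x^T D x = y^T y = 1 (generalized constraint)
      generalized = Y * s,
      random_walk = {
        X <- Y * s
        sweep(X, 2L, sqrt(colSums(X^2)), "/")
      })
  }
  vecs <- apply(vecs, 2L, .fixSign)
  # lambda_2 repeated on either side (including a second zero eigenvalue,
  # i.e. a disconnected graph) leaves the Fiedler vector defined only up to
  # rotation within the eigenspace
  scale <- max(abs(vals), 1e-300)
  degen <- n >= 3 &&
    ((vals[3] - vals[2]) < 1e-10 * scale ||
     (vals[2] - vals[1]) < 1e-10 * scale)
  new("EigenSolution", values = vals, vectors = vecs, problem = problem,
      degenerate = isTRUE(degen))
}

# sign convention: the component of largest magnitude ends positive; ties are
# broken by the first (lowest-index) such component
.fixSign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

#' The Fiedler pair: algebraic connectivity and its eigenvector
#'
#' Returns the second-smallest eigenvalue (the algebraic connectivity, zero
#' iff the graph is disconnected) and its eigenvector, the Fiedler vector,
#' whose components give the optimal one-dimensional embedding of the nodes.
#'
#' @param solution an [EigenSolution-class] with \code{n >= 2}.
#' @return list with elements \code{value} (\eqn{\lambda_2}) and
#'   \code{vector}.
#' @examples
#' fiedlerPair(solveEigenproblem(toyGraphs()$path3, "standard"))$value  # 1
#' @export
fiedlerPair <- function(solution) {
  validObject(solution)
  if (length(solution@values) < 2L)
    stop("Fiedler pair needs at least 2 nodes")
  if (solution@degenerate)
    warning("algebraic connectivity is a repeated eigenvalue; ",
            "the Fiedler vector is not unique")
  list(value = solution@values[2L], vector = solution@vectors[, 2L])
}

#' Spectral reordering of an embedding
#'
#' Replaces the Fiedler-vector values by their rank order (ascending), the
#' simplest way to map the embedding onto the anatomy as a heatmap.  Ranks
#' are invariant to any strictly increasing transform of the input; ties are
#' broken by node index, ascending (stable ordinal ranking).
#'
#' @param fiedlerVector numeric vector of embedding coordinates.
#' @return integer vector of ranks, a permutation of \code{1..n}.
#' @examples
#' spectralReorder(c(0.3, -0.1, 0.7))   # 2 1 3
#' @export
spectralReorder <- function(fiedlerVector) {
  if (any(!is.finite(fiedlerVector))) stop("embedding values must be finite")
  as.integer(rank(fiedlerVector, ties.method = "first"))
}

#' Embedding coordinates from a Laplacian eigendecomposition
#'
#' Takes eigenvectors 2..d+1 (the first, paired with eigenvalue 0, is
#' constant and carries no positional information) as the node coordinates
#' in a d-dimensional embedding: d = 1 is the Fiedler vector / principal
#' gradient, d = 2 adds the plane, and so on.
#'
#' @param solution an [EigenSolution-class].
#' @param d number of embedding dimensions, \code{1 <= d <= n - 1}.
#' @return \code{n x d} coordinate matrix.
#' @export
eigenmapCoords <- function(solution, d) {
  n <- length(solution@values)
  if (length(d) != 1L || is.na(d) || d < 1 || d > n - 1)
    stop(sprintf("d must be in [1, %d]", n - 1L))
  solution@vectors[, seq.int(2L, d + 1L), drop = FALSE]
}

#' Map 3-dimensional embedding coordinates to RGB colours
#'
#' Each coordinate column is min-max scaled to \eqn{[0, 1]} independently so
#' the three embedding dimensions drive the red, green and blue channels.
#' A constant (degenerate-range) column maps to 0.5.
#'
#' @param coords \code{n x 3} coordinate matrix.
#' @return \code{n x 3} matrix of RGB values in \eqn{[0, 1]}.
#' @export
rgbMap <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("rgbMap needs exactly 3 coordinate columns")
  apply(coords, 2L, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0.5, length(v))
    else (v - rng[1]) / diff(rng)
  })
}

#' Assemble a gradient map from an eigendecomposition
#'
#' Convenience wrapper bundling [eigenmapCoords()], [spectralReorder()] of
#' the first dimension, and (when \code{d >= 3}) the [rgbMap()] of the first
#' three dimensions into a [GradientMap-class].
#'
#' @inheritParams eigenmapCoords
#' @return a [GradientMap-class].
#' @export
gradientMap <- function(solution, d = 1L) {
  coords <- eigenmapCoords(solution, d)
  rgb <- if (d >= 3L) rgbMap(coords[, 1:3, drop = FALSE])
         else matrix(numeric(0), 0L, 3L)
  new("GradientMap", coords = coords,
      ranks = spectralReorder(coords[, 1L]), rgb = rgb)
}
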