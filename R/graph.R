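#' Node degrees of a weighted graph
#'
#' The degree of node \code{i} is the \code{i}-th row sum of the affinity
#' matrix.  For an unweighted (0/1) adjacency this is the number of adjacent
#' nodes; for a weighted graph it is the total edge weight incident to the
#' node.
#'
#' @param affinity an [AffinityMatrix-class] (or a plain matrix satisfying its
#'   invariants).
#' @return numeric vector of non-negative degrees, one per node.
#' @examples
#' g <- toyGraphs()
#' degreeMatrix(g$fig1)   # 3 2 2 1
#' @export
degreeMatrix <- function(affinity) {
  affinity <- .asAffinity(affinity)
  rowSums(affinity@.Data)
}

.asAffinity <- function(x) {
  if (is(x, "AffinityMatrix")) { validObject(x); x }
  else affinityMatrix(x)
}

#' Graph Laplacian of an affinity matrix
#'
#' Builds the unnormalized Laplacian \eqn{L = D - W}, the symmetric
#' normalized Laplacian \eqn{D^{-1/2} L D^{-1/2}} or the random-walk
#' normalized Laplacian \eqn{D^{-1} L}.  The normalized variants are
#' undefined at isolated nodes (degree 0): with \code{isolated = "error"}
#' (default) such input is rejected; with \code{isolated = "drop"} the
#' isolated nodes are removed and their original indices recorded in the
#' \code{dropped} attribute of the result.
#'
#' @param affinity an [AffinityMatrix-class] or plain matrix.
#' @param variant \code{"unnormalized"}, \code{"symmetric"} or
#'   \code{"random_walk"}.
#' @param isolated policy for degree-0 nodes under a normalized variant.
#' @return a [Laplacian-class] object; when nodes were dropped, their
#'   original indices are in the \code{dropped} slot.
#' @examples
#' L <- laplacianMatrix(toyGraphs()$fig1)
#' rowSums(L@matrix)          # all zero
#' @export
laplacianMatrix <- function(affinity,
                            variant = c("unnormalized", "symmetric",
                                        "random_walk"),
                            isolated = c("error", "drop")) {
  variant <- match.arg(variant)
  isolated <- match.arg(isolated)
  affinity <- .asAffinity(affinity)
  W <- affinity@.Data
  d <- rowSums(W)
  droppedHere <- integer(0)
  if (variant != "unnormalized" && any(d == 0)) {
    if (isolated == "error")
      stop("degenerate degree: isolated node(s) ",
           paste(which(d == 0), collapse = ", "),
           " under a normalized Laplacian variant")
    droppedHere <- which(d == 0)
    W <- W[-droppedHere, -droppedHere, drop = FALSE]
    d <- rowSums(W)
  }
  L <- diag(d, nrow = length(d)) - W
  if (variant == "symmetric") {
    s <- 1 / sqrt(d)
    L <- L * (s %o% s)
  } else if (variant == "random_walk") {
    L <- L / d
  }
  new("Laplacian", matrix = L, variant = variant, degrees = d,
      dropped = droppedHere)
}

#' Read / write an affinity matrix as plain CSV
#'
#' Debug-oriented plain comma-separated matrix exchange: no header, no row
#' names, one matrix row per line.
#'
#' @param path file path.
#' @return `readAffinityCsv()` an [AffinityMatrix-class].
#' @export
readAffinityCsv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  affinityMatrix(m)
}

#' @rdname readAffinityCsv
#' @param affinity matrix to write.
#' @export
writeAffinityCsv <- function(affinity, path) {
  utils::write.table(.asAffinity(affinity)@.Data, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
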