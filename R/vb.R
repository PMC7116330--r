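#' The Vogt-Bailey index of an affinity graph
#'
#' The VB index is the normalised algebraic connectivity of the graph
#' Laplacian: \eqn{\lambda_2} divided by the mean of all eigenvalues save the
#' first.  The denominator is the value \eqn{\lambda_2} would attain on a
#' graph whose affinity matrix is all ones, so the index is bounded in
#' \eqn{[0, 1]}: 1 means the region is perfectly homogeneous (uniform
#' affinity), 0 means a complete split exists (disconnected graph).  The
#' normalisation uses the eigenvalues of the same eigenproblem that produced
#' \eqn{\lambda_2}, which preserves the \eqn{[0, 1]} bound in every variant.
#'
#' @param affinity an [AffinityMatrix-class] or plain matrix, \code{n >= 3}.
#' @param problem eigenproblem to use; \code{"generalized"} is the default.
#' @param isolated policy for degree-0 nodes under a degree-normalised
#'   problem: \code{"error"} stops; \code{"drop"} treats the graph as what it
#'   is -- disconnected -- and returns 0 (an isolated node is a complete
#'   split that only the singular degree matrix prevents the solver from
#'   reporting itself).
#' @return a single value in \eqn{[0, 1]} (tiny negative floating-point
#'   results are clamped to 0), or \code{NA} when undefined.
#' @examples
#' W <- matrix(1, 5, 5); diag(W) <- 0
#' vbIndex(W)                       # 1: perfectly homogeneous
#' vbIndex(toyGraphs()$disjoint_edges, problem = "standard")  # 0: split
#' @export
vbIndex <- function(affinity,
                    problem = c("generalized", "standard",
                                "symmetric_normalized", "random_walk"),
                    isolated = c("error", "drop")) {
  problem <- match.arg(problem)
  isolated <- match.arg(isolated)
  affinity <- .asAffinity(affinity)
  W <- affinity@.Data
  if (nrow(W) < 3L)
    stop("VB index needs a neighbourhood of at least 3 nodes")
  d <- rowSums(W)
  if (all(d == 0)) {
    warning("all weights are zero; VB index of the empty graph is 0")
    return(0)
  }
  if (problem != "standard" && any(d == 0)) {
    if (isolated == "error")
      stop("degenerate degree: isolated node(s) ",
           paste(which(d == 0), collapse = ", "),
           "; use isolated = \"drop\" to remove them")
    # an isolated node means the graph is already split: the algebraic
    # connectivity of the full graph is 0, which D-singularity merely hides
    return(0)
  }
  sol <- solveEigenproblem(affinityMatrix(W), problem)
  vals <- sol@values
  vb <- vals[2L] / mean(vals[-1L])
  min(1, max(0, vb))
}

#' Whole-region gradient and VB index
#'
#' Builds one affinity graph over all nodes, extracts a d-dimensional
#' gradient map and computes the single VB index of the whole region
#' ("full brain" analysis).
#'
#' @param features \code{n x T} feature matrix, one vector per node.
#' @param policy an [affinityPolicy()].
#' @param problem eigenproblem; the generalized problem is the default.
#' @param d embedding dimensions for the gradient map.
#' @param isolated isolated-node policy, see [vbIndex()].
#' @return a [VBResult-class] with \code{mode = "full"}.
#' @examples
#' f <- rbind(matrix(rnorm(60), 3, 20)[rep(1:3, each = 4), ])
#' res <- fullAnalysis(f + rnorm(length(f), sd = 0.01), d = 1)
#' vbValues(res)
#' @export
fullAnalysis <- function(features, policy = affinityPolicy(),
                         problem = c("generalized", "standard",
                                     "symmetric_normalized", "random_walk"),
                         d = 3L, isolated = c("error", "drop")) {
  problem <- match.arg(problem)
  isolated <- match.arg(isolated)
  W <- buildAffinity(features, policy)
  deg <- rowSums(W@.Data)
  if (problem != "standard" && any(deg == 0) && isolated == "drop") {
    keep <- which(deg > 0)
    W <- affinityMatrix(W@.Data[keep, keep, drop = FALSE],
                        dropped = sort(c(W@dropped, setdiff(seq_along(deg), keep))))
  }
  d <- min(d, nrow(W) - 1L)
  sol <- solveEigenproblem(W, problem)
  grad <- gradientMap(sol, d)
  vals <- sol@values
  vb <- min(1, max(0, vals[2L] / mean(vals[-1L])))
  new("VBResult", mode = "full", vb = vb, gradient = grad,
      problem = problem, neighborhoodSizes = integer(0))
}

#' Per-cluster gradients and VB indices
#'
#' Restricts the analysis to each cluster (region of interest) in turn: the
#' affinity matrix is built from the member nodes only, yielding one gradient
#' map and one VB index per cluster.  Clusters with fewer than 3 members get
#' \code{NA} with a warning.  Label 0 means unassigned and is skipped.
#'
#' @inheritParams fullAnalysis
#' @param labels length-n vector of non-negative integer cluster labels,
#'   0 = unassigned.
#' @return a [VBResult-class] with \code{mode = "clustered"}; \code{vb} is
#'   named by cluster id and \code{gradient} is a named list of
#'   [GradientMap-class] objects (\code{NULL} entries where undefined).
#' @export
clusteredAnalysis <- function(features, labels, policy = affinityPolicy(),
                              problem = c("generalized", "standard",
                                          "symmetric_normalized",
                                          "random_walk"),
                              d = 1L, isolated = c("error", "drop")) {
  problem <- match.arg(problem)
  isolated <- match.arg(isolated)
  features <- as.matrix(features)
  if (length(labels) != nrow(features))
    stop(sprintf("labels length (%d) must match feature rows (%d)",
                 length(labels), nrow(features)))
  ids <- sort(unique(labels[labels > 0]))
  vb <- stats::setNames(rep(NA_real_, length(ids)), ids)
  grads <- stats::setNames(vector("list", length(ids)), ids)
  for (id in as.character(ids)) {
    members <- which(labels == as.integer(id))
    if (length(members) < 3L) {
      warning(sprintf("cluster %s has %d < 3 members; VB index undefined",
                      id, length(members)))
      next
    }
    sub <- fullAnalysis(features[members, , drop = FALSE], policy, problem,
                        d = min(d, length(members) - 1L), isolated = isolated)
    vb[[id]] <- sub@vb
    grads[[id]] <- sub@gradient
  }
  new("VBResult", mode = "clustered", vb = vb, gradient = grads,
      problem = problem, neighborhoodSizes = integer(0))
}

#' Expand per-cluster values to a per-vertex map
#'
#' @param result a clustered [VBResult-class].
#' @param labels the cluster-label vector the analysis was run with.
#' @return length-n numeric vector: each vertex carries its cluster's VB
#'   index (\code{NA} where unassigned or undefined).
#' @export
expandToVertices <- function(result, labels) {
  if (result@mode != "clustered")
    stop("expandToVertices() applies to clustered results")
  out <- rep(NA_real_, length(labels))
  for (id in names(result@vb)) {
    out[labels == as.integer(id)] <- result@vb[[id]]
  }
  out
}

#' Vertex-wise searchlight VB index
#'
#' For every masked vertex, the searchlight neighbourhood is the vertex plus
#' its one-ring mesh neighbours (intersected with the mask); the VB index of
#' the neighbourhood's affinity graph is assigned to the centre vertex.  With
#' 5-6 one-ring neighbours on a typical cortical mesh this acts as a local
#' edge detector: low values flag vertices sitting on a feature boundary,
#' values near 1 flag homogeneous neighbourhoods.  Neighbourhoods reduced
#' below 3 vertices (mask borders, orphan vertices) yield \code{NA} rather
#' than an error.
#'
#' @inheritParams fullAnalysis
#' @param mesh a [SurfaceMesh-class] with one vertex per feature row.
#' @param mask optional logical/0-1 vector of vertices to analyse (e.g.
#'   cortex without the medial wall); default all.
#' @param jobs number of worker processes for [parallelMap()]; results are
#'   identical to serial execution.
#' @return a [VBResult-class] with \code{mode = "searchlight"}: per-vertex
#'   \code{vb} and \code{neighborhoodSizes}.
#' @export
searchlightAnalysis <- function(features, mesh, mask = NULL,
                                policy = affinityPolicy(),
                                problem = c("generalized", "standard",
                                            "symmetric_normalized",
                                            "random_walk"),
                                isolated = c("drop", "error"), jobs = 1L) {
  problem <- match.arg(problem)
  isolated <- match.arg(isolated)
  features <- as.matrix(features)
  n <- nVertices(mesh)
  if (nrow(features) != n)
    stop(sprintf("alignment error: %d feature rows but %d mesh vertices",
                 nrow(features), n))
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n)
    stop(sprintf("alignment error: mask length %d but %d mesh vertices",
                 length(mask), n))
  mask <- as.logical(mask)
  ring <- oneRing(mesh)

  centre <- which(mask)
  res <- parallelMap(centre, function(v) {
    nb <- c(v, ring[[v]])
    nb <- nb[mask[nb]]
    if (length(nb) < 3L) return(list(vb = NA_real_, size = length(nb)))
    w <- tryCatch(
      buildAffinity(features[nb, , drop = FALSE], policy,
                    degenerate = "zero"),
      error = function(e) NULL)
    if (is.null(w)) return(list(vb = NA_real_, size = length(nb)))
    vb <- suppressWarnings(vbIndex(w, problem, isolated = isolated))
    list(vb = vb, size = length(nb))
  }, jobs = jobs)

  vb <- rep(NA_real_, n)
  sizes <- integer(n)
  vb[centre] <- vapply(res, `[[`, numeric(1), "vb")
  sizes[centre] <- vapply(res, `[[`, integer(1), "size")
  new("VBResult", mode = "searchlight", vb = vb, gradient = NULL,
      problem = problem, neighborhoodSizes = sizes)
}
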