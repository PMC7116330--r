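#' Partition a mesh into contiguous parcels
#'
#' Splits the vertices of a closed mesh into \code{nParcels} non-empty,
#' contiguous parcels (connected in the one-ring graph).  Parcel centres are
#' chosen by farthest-point sampling in hop distance from a seeded random
#' start; vertices are then assigned by multi-source breadth-first region
#' growing, which guarantees each parcel is connected.  Identical seeds give
#' identical labels.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param nParcels number of parcels, \code{2 <= nParcels <= n/10} (1 is
#'   allowed and labels everything 1).
#' @param seed integer RNG seed for the initial centre.
#' @param mask optional logical vector; masked-out vertices get label 0.
#' @return integer vector of labels \code{1..nParcels} (0 where masked out).
#' @examples
#' labels <- parcellateMesh(makeIcosphere(2), 6, seed = 1)
#' table(labels)
#' @export
parcellateMesh <- function(mesh, nParcels, seed = 1L, mask = NULL) {
  n <- nVertices(mesh)
  if (nParcels < 1L) stop("nParcels must be >= 1")
  if (nParcels > 1L && nParcels > n / 10)
    stop(sprintf("nParcels = %d too large for %d vertices (max n/10)",
                 nParcels, n))
  if (is.null(mask)) mask <- rep(TRUE, n)
  mask <- as.logical(mask)
  ring <- oneRing(mesh)
  labels <- integer(n)
  inside <- which(mask & lengths(ring) > 0)
  if (nParcels == 1L) { labels[inside] <- 1L; return(labels) }

  bfsDist <- function(start) {
    dist <- rep(NA_integer_, n)
    dist[start] <- 0L
    frontier <- start
    while (length(frontier)) {
      nxt <- setdiff(unlist(ring[frontier], use.names = FALSE),
                     which(!is.na(dist)))
      nxt <- nxt[mask[nxt]]
      if (!length(nxt)) break
      dist[nxt] <- dist[frontier[1]] + 1L
      frontier <- nxt
    }
    dist
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  centres <- sample(inside, 1L)
  dmin <- bfsDist(centres)
  while (length(centres) < nParcels) {
    cand <- inside[which.max(replace(dmin, is.na(dmin), -1L)[inside])]
    if (cand %in% centres)
      stop("impossible contiguity: cannot place that many parcels")
    centres <- c(centres, cand)
    dmin <- pmin(dmin, bfsDist(cand), na.rm = TRUE)
  }

  # round-robin multi-source BFS growth: deterministic, regions stay connected
  labels[centres] <- seq_len(nParcels)
  frontiers <- as.list(centres)
  repeat {
    grew <- FALSE
    for (p in seq_len(nParcels)) {
      if (!length(frontiers[[p]])) next
      nxt <- unique(unlist(ring[frontiers[[p]]], use.names = FALSE))
      nxt <- nxt[mask[nxt] & labels[nxt] == 0L]
      if (length(nxt)) {
        labels[nxt] <- p
        grew <- TRUE
      }
      frontiers[[p]] <- nxt
    }
    if (!grew) break
  }
  # orphan/unreached masked vertices stay 0 only if disconnected from all
  # centres; on closed meshes everything is reached
  labels
}

#' Synthetic parcellated time series
#'
#' Generates the ground-truth feature matrix for the synthetic surface
#' experiment: one base time series per parcel, every vertex receiving its
#' parcel's series plus (optional) independent Gaussian noise.  The base
#' series are built from an orthonormalised common component plus per-parcel
#' unique components inside the mean-centred subspace: series \code{k} is
#' \eqn{a_k q_0 + \sqrt{1 - a_k^2}\, q_k} with orthonormal centred
#' \eqn{q_i}, so the sample Pearson correlation of series \code{j} and
#' \code{k} is exactly \eqn{a_j a_k}.  The loadings \eqn{a_k} are jittered
#' around \eqn{\sqrt{crossCorr}} (pairwise correlations stay within
#' \eqn{\pm 0.05} of \code{crossCorr}): perfectly identical cross
#' correlations would give the affinity graph an artificial parcel-exchange
#' symmetry, with degenerate eigenvectors, that differing real time series
#' do not have.  With \code{noiseSd = 0} all vertices of a parcel carry
#' identical copies -- the exact-copy design of the synthetic validation
#' experiment.
#'
#' @param labels integer parcel labels (0 = unassigned; those vertices get
#'   independent noise-only series).
#' @param seriesLength number of timepoints, \code{>= 8}.
#' @param crossCorr target correlation between distinct parcels' base series,
#'   in \code{[0, 0.9]}.
#' @param noiseSd standard deviation of per-vertex additive noise (the base
#'   series have unit norm scaled to sd 1).
#' @param seed integer RNG seed; identical arguments give bit-identical
#'   output.
#' @return \code{n x seriesLength} numeric matrix.
#' @examples
#' labels <- parcellateMesh(makeIcosphere(2), 6, seed = 1)
#' f <- parcelTimeseries(labels, 200, crossCorr = 0.3, seed = 1)
#' r <- cor(t(f[match(1:6, labels), ]))
#' range(r[upper.tri(r)])       # all within 0.3 +/- 0.05
#' @export
parcelTimeseries <- function(labels, seriesLength = 200L, crossCorr = 0.3,
                             noiseSd = 0, seed = 1L) {
  if (seriesLength < 8L) stop("seriesLength must be >= 8")
  if (crossCorr < 0 || crossCorr > 0.9)
    stop("crossCorr must be in [0, 0.9]")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  labels <- as.integer(labels)
  ids <- sort(unique(labels[labels > 0]))
  K <- length(ids)
  if (seriesLength < K + 2L)
    stop(sprintf("infeasible: %d parcels need seriesLength > %d",
                 K, K + 1L))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  # orthonormal basis of K+1 centred directions: column 1 is the shared
  # component, columns 2..K+1 are parcel-unique
  M <- matrix(stats::rnorm(seriesLength * (K + 1L)), seriesLength)
  M <- scale(M, scale = FALSE)
  Q <- qr.Q(qr(M))
  # corr(base_j, base_k) = a_j * a_k; jittered loadings keep it within
  # +/-0.05 of crossCorr while breaking exact parcel exchangeability
  h <- 0.02 / max(crossCorr, 0.1)   # keeps |a_j a_k - crossCorr| < 0.05
  a <- sqrt(crossCorr) * (1 + stats::runif(K, -h, h))
  base <- Q[, 1] %o% a +
          t(sqrt(1 - a^2) * t(Q[, -1, drop = FALSE]))
  # scale each base series to sd 1 so noiseSd is on a comparable scale
  base <- t(t(base) / apply(base, 2L, stats::sd))

  out <- matrix(stats::rnorm(length(labels) * seriesLength, sd = max(noiseSd, 1)),
                length(labels), seriesLength)
  out[labels > 0, ] <- 0
  for (k in seq_len(K)) {
    rows <- which(labels == ids[k])
    out[rows, ] <- matrix(base[, k], length(rows), seriesLength, byrow = TRUE)
  }
  if (noiseSd > 0) {
    idx <- which(labels > 0)
    out[idx, ] <- out[idx, ] +
      matrix(stats::rnorm(length(idx) * seriesLength, sd = noiseSd),
             length(idx), seriesLength)
  }
  out
}

#' Toy affinity-matrix fixtures
#'
#' Small named graphs with known spectra, used throughout the tests and
#' examples:
#' \describe{
#'   \item{fig1}{the 4-node unweighted graph with edges a-b, a-c, a-d, b-c;
#'     degree sequence (3, 2, 2, 1), Laplacian eigenvalues (0, 1, 3, 4).}
#'   \item{path3}{the path a-b-c; algebraic connectivity 1.}
#'   \item{k4}{the complete unit-weight graph on 4 nodes.}
#'   \item{disjoint_edges}{two disjoint unit-weight edges; disconnected, so
#'     the algebraic connectivity is 0.}
#'   \item{uniform4 .. uniform10}{all-ones (off-diagonal) affinities, the
#'     graphs whose VB index is exactly 1.}
#' }
#'
#' @return named list of [AffinityMatrix-class] objects.
#' @export
toyGraphs <- function() {
  edgeGraph <- function(n, edges) {
    W <- matrix(0, n, n)
    for (e in edges) W[e[1], e[2]] <- W[e[2], e[1]] <- 1
    affinityMatrix(W)
  }
  uniform <- function(n) {
    W <- matrix(1, n, n); diag(W) <- 0
    affinityMatrix(W)
  }
  out <- list(
    fig1 = edgeGraph(4, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3))),
    path3 = edgeGraph(3, list(c(1, 2), c(2, 3))),
    k4 = uniform(4),
    disjoint_edges = edgeGraph(4, list(c(1, 2), c(3, 4))))
  for (n in 4:10) out[[paste0("uniform", n)]] <- uniform(n)
  out
}

#' Deterministic test images
#'
#' Small RGB rasters with known edge structure for the pixel-searchlight
#' demonstration: \code{"two_tone"} has a single straight vertical boundary
#' at column \code{floor(size/2)}; \code{"gradient_ramp"} varies smoothly
#' with no sharp boundary; \code{"blocks"} is a 2 x 2 partition of four
#' distinctly coloured quadrants.
#'
#' @param kind image family.
#' @param size side length in pixels, \code{>= 8}.
#' @param seed RNG seed (reserved for future noisy variants; current images
#'   are fully deterministic and identical across seeds).
#' @return \code{size x size x 3} array with values in \eqn{[0, 1]}.
#' @export
testImage <- function(kind = c("two_tone", "gradient_ramp", "blocks"),
                      size = 16L, seed = 1L) {
  kind <- match.arg(kind)
  if (size < 8L) stop("size must be >= 8")
  img <- array(0, c(size, size, 3))
  half <- floor(size / 2)
  if (kind == "two_tone") {
    img[, seq_len(half), ] <- rep(c(0.9, 0.2, 0.1), each = size * half)
    img[, (half + 1):size, ] <-
      rep(c(0.1, 0.3, 0.9), each = size * (size - half))
  } else if (kind == "gradient_ramp") {
    ramp <- (col(matrix(0, size, size)) - 1) / (size - 1)
    img[, , 1] <- ramp
    img[, , 2] <- 0.5
    img[, , 3] <- 1 - ramp
  } else {
    cols <- list(c(0.9, 0.1, 0.1), c(0.1, 0.9, 0.1),
                 c(0.1, 0.1, 0.9), c(0.9, 0.9, 0.1))
    quad <- function(r, c) cols[[2 * (r - 1) + c]]
    for (r in 1:2) for (cc in 1:2) {
      ri <- if (r == 1) seq_len(half) else (half + 1):size
      ci <- if (cc == 1) seq_len(half) else (half + 1):size
      img[ri, ci, ] <- rep(quad(r, cc), each = length(ri) * length(ci))
    }
  }
  img
}
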