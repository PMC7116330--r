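#' Similarity measures between feature vectors
#'
#' The family of pairwise similarity measures used to weight feature
#' similarity graphs, in increasing order of invariance:
#' \describe{
#'   \item{`dotProduct`}{\eqn{\sum_i x_i y_i = \|x\|\|y\|\cos(x,y)}; confounds
#'     magnitude with angle.}
#'   \item{`cosineSimilarity`}{the dot product normalised by both magnitudes;
#'     scale-invariant but sensitive to constant shifts.}
#'   \item{`pearsonSimilarity`}{cosine similarity of the mean-centred vectors,
#'     i.e. the sample Pearson correlation; shift- and scale-invariant.}
#'   \item{`normAngle`}{the centred angle \eqn{\arccos(\mathrm{corr})}
#'     normalised by 90 degrees, bounded in \eqn{[0, 2]}: 0 = collinear,
#'     1 = orthogonal, 2 = anti-collinear.}
#'   \item{`angSim`}{\eqn{1 - \mathrm{normAngle}}, in \eqn{[-1, 1]}.  Unlike
#'     the correlation it is linear in the centred angle, so +0.5 means
#'     exactly half way between orthogonal and collinear (45 degrees) and
#'     -0.5 half way between orthogonal and anti-collinear (135 degrees).}
#' }
#'
#' @param x,y numeric vectors of equal length with finite entries.
#' @return a single numeric similarity value.
#' @examples
#' x <- c(1, 2, 3, 4)
#' pearsonSimilarity(x, 2 * x + 7)   # 1: shift- and scale-invariant
#' angSim(x, -x)                     # -1: anti-collinear
#' @export
dotProduct <- function(x, y) {
  .checkPair(x, y)
  sum(x * y)
}

.checkPair <- function(x, y) {
  if (length(x) != length(y))
    stop(sprintf("feature vectors differ in length (%d vs %d)",
                 length(x), length(y)))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("feature vectors must be finite")
  invisible(TRUE)
}

#' @rdname dotProduct
#' @export
cosineSimilarity <- function(x, y) {
  .checkPair(x, y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("degenerate feature: zero-norm vector has no direction")
  sum(x * y) / (nx * ny)
}

#' @rdname dotProduct
#' @export
pearsonSimilarity <- function(x, y) {
  .checkPair(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate feature: constant vector has undefined correlation")
  stats::cor(x, y)
}

# correlations can exceed [-1,1] by floating point; clamp before arccos
.clampCorr <- function(r, tol = 1e-12) {
  if (any(r > 1 + tol | r < -1 - tol, na.rm = TRUE))
    stop("correlation outside [-1, 1] beyond floating-point tolerance")
  pmin(1, pmax(-1, r))
}

# angular transform of a correlation: 1 - arccos(r) / (pi/2), in [-1, 1]
.angOfCorr <- function(r) 1 - acos(.clampCorr(r)) * 2 / pi

#' @rdname dotProduct
#' @export
normAngle <- function(x, y) {
  r <- pearsonSimilarity(x, y)
  acos(.clampCorr(r)) * 2 / pi
}

#' @rdname dotProduct
#' @export
angSim <- function(x, y) 1 - normAngle(x, y)

#' Build a non-negative affinity matrix from feature vectors
#'
#' Computes the pairwise similarity between all rows of \code{features} and
#' assembles a valid [AffinityMatrix-class] under the given
#' [affinityPolicy()].  The default policy reproduces the recipe used for
#' whole-cortex resting-state analyses: Pearson correlation, negative
#' correlations set to zero, and the retained values mapped through the
#' angular similarity transform \eqn{r \mapsto 1 - \arccos(r) \cdot 2/\pi},
#' giving weights in \eqn{[0, 1]} with no shift constant.
#'
#' Constant (zero-variance) feature rows have undefined correlation; with
#' \code{degenerate = "exclude"} (default) they are removed and their indices
#' recorded in the result's \code{dropped} slot, with \code{"zero"} they are
#' kept as isolated nodes (all weights 0).
#'
#' @param features numeric \code{n x T} matrix: one feature vector (e.g. an
#'   fMRI time series) per row; \code{T >= 2}.
#' @param policy an [AffinityPolicy-class]; see [affinityPolicy()].
#' @param degenerate policy for zero-variance rows.
#' @return an [AffinityMatrix-class].
#' @examples
#' f <- matrix(rnorm(5 * 20), 5)
#' W <- buildAffinity(f)
#' range(W)                      # within [0, 1]
#' @export
buildAffinity <- function(features, policy = affinityPolicy(),
                          degenerate = c("exclude", "zero")) {
  degenerate <- match.arg(degenerate)
  validObject(policy)
  features <- as.matrix(features)
  if (ncol(features) < 2L)
    stop("features need at least 2 columns (feature dimensions)")
  if (any(!is.finite(features))) stop("features must be finite")

  n0 <- nrow(features)
  needsVariance <- policy@metric %in% c("pearson", "ang_sim")
  zeroRows <- if (needsVariance) {
    which(apply(features, 1L, stats::sd) == 0)
  } else if (policy@metric == "cosine") {
    which(rowSums(features^2) == 0)
  } else integer(0)

  dropped <- integer(0)
  zeroOut <- integer(0)
  if (length(zeroRows)) {
    if (degenerate == "exclude") {
      dropped <- zeroRows
      features <- features[-zeroRows, , drop = FALSE]
    } else {
      zeroOut <- zeroRows
    }
  }
  keep <- setdiff(seq_len(nrow(features)), zeroOut)
  if (length(keep) < 3L)
    stop("need at least 3 non-degenerate nodes to build an affinity graph")

  S <- matrix(0, nrow(features), nrow(features))
  fs <- features[keep, , drop = FALSE]
  S[keep, keep] <- switch(policy@metric,
    dot = tcrossprod(fs),
    cosine = {
      u <- fs / sqrt(rowSums(fs^2))
      tcrossprod(u)
    },
    pearson = .clampCorr(stats::cor(t(fs))),
    # the angular transform is strictly increasing and fixes 0 and 1, so
    # clamping negative correlations before or after it is equivalent; the
    # default recipe (clamp, then transform retained values) is this line
    # composed with zero_negatives below, and yields weights in [0, 1]
    ang_sim = .angOfCorr(stats::cor(t(fs)))
  )

  S[keep, keep] <- switch(policy@negativity,
    zero_negatives = pmax(S[keep, keep], 0),
    shift_constant = S[keep, keep] + policy@shift,
    none = S[keep, keep]
  )
  if (any(S[upper.tri(S)] < 0))
    stop("negative weights remain after the '", policy@negativity,
         "' policy; use zero_negatives or a larger shift")
  diag(S) <- 0

  if (!is.na(policy@thresholdEps)) S[S < policy@thresholdEps] <- 0
  if (!is.na(policy@knnK)) S <- .knnSparsify(S, policy@knnK)
  if (policy@binarize) S <- (S > 0) + 0

  if (all(S == 0))
    warning("affinity graph is fully disconnected (all weights 0)")
  affinityMatrix(S, dropped = c(dropped))
}

# keep each row's k largest weights; symmetrise by union so w_ij survives if
# j is in i's top-k OR i is in j's top-k
.knnSparsify <- function(S, k) {
  n <- nrow(S)
  keepMask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(S[i, ], decreasing = TRUE)
    top <- ord[seq_len(min(k, n - 1L))]
    keepMask[i, top[S[i, top] > 0]] <- TRUE
  }
  keepMask <- keepMask | t(keepMask)
  S * keepMask
}

#' Read a feature matrix from CSV
#'
#' Plain CSV with one node (vertex) per row and one feature dimension (e.g.
#' timepoint) per column, no header.
#'
#' @param path file path.
#' @return numeric matrix, nodes in rows.
#' @export
readFeaturesCsv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' @rdname readFeaturesCsv
#' @param features matrix to write.
#' @export
writeFeaturesCsv <- function(features, path) {
  utils::write.table(features, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
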