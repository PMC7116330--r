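# Shared fixtures, built in code at test time.

# random valid affinity: symmetric, non-negative, zero diagonal
randomAffinity <- function(n, density = 0.7) {
  W <- matrix(stats::runif(n * n), n)
  W[W > density] <- 0
  W <- (W + t(W)) / 2
  diag(W) <- 0
  affinityMatrix(W)
}

# features with a given number of identical-series groups (no noise)
groupedFeatures <- function(sizes, T = 40, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(length(sizes) * T), length(sizes))
  base[rep(seq_along(sizes), sizes), , drop = FALSE]
}

# two groups of mutually orthogonal (zero-correlation) centred series
orthogonalGroups <- function(nPer = 3, T = 40, seed = 1) {
  set.seed(seed)
  M <- scale(matrix(rnorm(T * 2), T), scale = FALSE)
  Q <- qr.Q(qr(M))
  rbind(matrix(Q[, 1], nPer, T, byrow = TRUE),
        matrix(Q[, 2], nPer, T, byrow = TRUE))
}

# brute-force generalized eigenvalues via the nonsymmetric solver on D^-1 L:
# an independent route to the same spectrum
bruteGeneralizedValues <- function(W) {
  d <- rowSums(W)
  L <- diag(d) - W
  sort(Re(eigen(diag(1 / d) %*% L)$values))
}

# direct double-loop embedding cost  sum_{i<j} W_ij (x_i - x_j)^2
bruteCost <- function(W, x) {
  n <- nrow(W)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + W[i, j] * (x[i] - x[j])^2
  s
}

expect_symmetric <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), tol)
}
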