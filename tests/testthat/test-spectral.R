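test_that("standard problem reproduces the printed graph's spectrum {0,1,3,4}", {
  es <- solveEigenproblem(toyGraphs()$fig1, "standard")
  expect_equal(eigenValues(es), c(0, 1, 3, 4), tolerance = 1e-10)
  # smallest eigenvalue pairs with a constant eigenvector
  v1 <- eigenVectors(es)[, 1]
  expect_lt(diff(range(v1)), 1e-10)
})

test_that("eigenpairs satisfy the residual contract for every problem", {
  set.seed(21)
  W <- randomAffinity(10)
  W@.Data[W@.Data == 0] <- 0.02; diag(W@.Data) <- 0
  L <- laplacianMatrix(W)
  d <- L@degrees
  for (prob in c("standard", "generalized", "symmetric_normalized",
                 "random_walk")) {
    es <- solveEigenproblem(L, prob)
    B <- switch(prob, standard = diag(10), generalized = diag(d),
                symmetric_normalized = diag(10), random_walk = diag(10))
    A <- switch(prob,
      standard = L@matrix,
      generalized = L@matrix,
      symmetric_normalized = laplacianMatrix(W, "symmetric")@matrix,
      random_walk = laplacianMatrix(W, "random_walk")@matrix)
    res <- A %*% eigenVectors(es) -
      B %*% eigenVectors(es) %*% diag(eigenValues(es))
    expect_lt(max(abs(res)), 1e-6 * norm(A, "2"))
  }
})

test_that("generalized eigenvectors obey the degree-weighted constraint", {
  set.seed(22)
  W <- randomAffinity(8)
  W@.Data[W@.Data == 0] <- 0.1; diag(W@.Data) <- 0
  es <- solveEigenproblem(W, "generalized")
  D <- diag(degreeMatrix(W))
  gram <- t(eigenVectors(es)) %*% D %*% eigenVectors(es)
  expect_equal(diag(gram), rep(1, 8), tolerance = 1e-8)
  expect_lt(max(abs(gram - diag(8))), 1e-8)
})

test_that("generalized eigenvalues equal the random-walk (D^-1 L) spectrum", {
  set.seed(23)
  for (i in 1:10) {
    W <- randomAffinity(7)
    W@.Data[W@.Data == 0] <- 0.05; diag(W@.Data) <- 0
    es <- solveEigenproblem(W, "generalized")
    expect_equal(eigenValues(es), bruteGeneralizedValues(W@.Data),
                 tolerance = 1e-8)
  }
})

test_that("Fiedler pair: closed forms for the 3-path and complete graphs", {
  fp <- fiedlerPair(solveEigenproblem(toyGraphs()$path3, "standard"))
  expect_equal(fp$value, 1, tolerance = 1e-10)
  v <- fp$vector / fp$vector[1]
  expect_equal(v, c(1, 0, -1), tolerance = 1e-8)
  # complete unit-weight graph on n nodes: L = nI - J, lambda_2 = n
  # (repeated n times, so the uniqueness warning is expected)
  for (n in c(4, 6, 9)) {
    W <- matrix(1, n, n); diag(W) <- 0
    expect_warning(
      fp <- fiedlerPair(solveEigenproblem(affinityMatrix(W), "standard")),
      "not unique")
    expect_equal(fp$value, n, tolerance = 1e-8)
  }
  expect_warning(
    fp <- fiedlerPair(solveEigenproblem(toyGraphs()$disjoint_edges,
                                        "standard")),
    "not unique")
  expect_equal(fp$value, 0, tolerance = 1e-10)
})

test_that("Fiedler pair minimises the constrained embedding cost (variational oracle)", {
  set.seed(24)
  W <- randomAffinity(9)
  W@.Data[W@.Data == 0] <- 0.05; diag(W@.Data) <- 0
  L <- laplacianMatrix(W)@matrix
  d <- degreeMatrix(W)
  for (prob in c("standard", "generalized")) {
    es <- solveEigenproblem(affinityMatrix(W@.Data), prob)
    l2 <- eigenValues(es)[2]
    triv <- if (prob == "standard") rep(1, 9) else rep(1, 9)  # ker(L)
    B <- if (prob == "standard") diag(9) else diag(d)
    for (i in 1:100) {
      v <- rnorm(9)
      v <- v - triv * sum(v * (B %*% triv)) / sum(triv * (B %*% triv))
      rayleigh <- sum(v * (L %*% v)) / sum(v * (B %*% v))
      expect_gte(rayleigh, l2 - 1e-8)
    }
  }
})

test_that("x^T L x equals the double-loop cost sum W_ij (x_i - x_j)^2", {
  set.seed(25)
  for (i in 1:20) {
    W <- randomAffinity(8)
    L <- laplacianMatrix(W)@matrix
    x <- rnorm(8)
    expect_equal(drop(t(x) %*% L %*% x), bruteCost(W@.Data, x),
                 tolerance = 1e-8)
  }
})

test_that("the Fiedler sign exactly partitions a two-block affinity", {
  blockW <- function(n1, n2, cross) {
    W <- matrix(cross, n1 + n2, n1 + n2)
    W[1:n1, 1:n1] <- 1
    W[(n1 + 1):(n1 + n2), (n1 + 1):(n1 + n2)] <- 1
    diag(W) <- 0
    affinityMatrix(W)
  }
  for (prob in c("standard", "generalized")) {
    fp <- fiedlerPair(solveEigenproblem(blockW(5, 4, 0.1), prob))
    s <- sign(fp$vector)
    expect_true(all(s[1:5] == s[1]) && all(s[6:9] == -s[1]))
  }
})

test_that("eigenvector sign convention makes maps reproducible", {
  set.seed(26)
  W <- randomAffinity(8)
  es <- solveEigenproblem(W, "standard")
  for (j in 2:8) {
    v <- eigenVectors(es)[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("spectral reordering is rank order with stable index tie-breaks", {
  expect_equal(spectralReorder(c(0.3, -0.1, 0.7)), c(2L, 1L, 3L))
  set.seed(27)
  v <- rnorm(20)
  expect_equal(spectralReorder(v), spectralReorder(exp(v)))
  expect_equal(spectralReorder(c(1, 0.5, 0.5, 0)), c(4L, 2L, 3L, 1L))
})

test_that("eigenmap coordinates: dimensions, block structure, orthogonality", {
  es <- solveEigenproblem(toyGraphs()$fig1, "standard")
  expect_equal(eigenmapCoords(es, 1)[, 1],
               fiedlerPair(es)$vector)
  expect_error(eigenmapCoords(es, 4), "d must be")
  expect_error(eigenmapCoords(es, 0), "d must be")

  # 6-parcel block features -> coordinates piecewise constant per parcel
  f <- groupedFeatures(rep(4, 6), T = 50, seed = 9)
  sol <- solveEigenproblem(buildAffinity(f), "generalized")
  coords <- eigenmapCoords(sol, 3)
  for (j in 1:3) for (p in 1:6) {
    vals <- coords[(4 * p - 3):(4 * p), j]
    expect_lt(diff(range(vals)), 1e-6)
  }
})

test_that("rgb mapping min-max scales channels and handles degenerate ranges", {
  rgb <- rgbMap(cbind(c(-1, 0, 1), c(5, 5, 5), c(0, 10, 5)))
  expect_equal(rgb[, 1], c(0, 0.5, 1))
  expect_equal(rgb[, 2], rep(0.5, 3))
  expect_equal(range(rgb[, 3]), c(0, 1))
  # permuting nodes permutes colours identically
  set.seed(28)
  coords <- matrix(rnorm(30), 10, 3)
  p <- sample(10)
  expect_equal(rgbMap(coords[p, ]), rgbMap(coords)[p, ])
})

test_that("gradientMap bundles coords, ranks and rgb consistently", {
  set.seed(29)
  f <- matrix(rnorm(8 * 30), 8)
  sol <- solveEigenproblem(buildAffinity(f), "generalized")
  gm <- gradientMap(sol, 3)
  expect_s4_class(gm, "GradientMap")
  expect_equal(gradientRanks(gm), spectralReorder(gradientCoords(gm)[, 1]))
  expect_equal(dim(gradientRGB(gm)), c(8L, 3L))
  gm1 <- gradientMap(sol, 1)
  expect_equal(nrow(gradientRGB(gm1)), 0L)
})

test_that("a repeated Fiedler value raises the degeneracy flag downstream", {
  # disjoint edges: eigenvalues 0,0,2,2 under the standard problem
  es <- solveEigenproblem(toyGraphs()$disjoint_edges, "standard")
  expect_true(es@degenerate)
  expect_warning(fiedlerPair(es), "not unique")
})
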