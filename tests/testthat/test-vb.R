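test_that("vbIndex fixed points: uniform graph 1, disconnected 0, printed graph 0.375", {
  g <- toyGraphs()
  for (prob in c("standard", "generalized")) {
    expect_equal(vbIndex(g$uniform6, prob), 1, tolerance = 1e-10)
    expect_equal(vbIndex(g$k4, prob), 1, tolerance = 1e-10)
  }
  expect_equal(vbIndex(g$disjoint_edges, "standard"), 0, tolerance = 1e-10)
  # eigenvalues {0,1,3,4} -> 1 / mean(1,3,4) = 0.375
  expect_equal(vbIndex(g$fig1, "standard"), 0.375, tolerance = 1e-10)
  expect_error(vbIndex(affinityMatrix(matrix(0, 2, 2))), "at least 3")
})

test_that("vbIndex is invariant to positive rescaling of the affinity", {
  set.seed(31)
  for (i in 1:20) {
    W <- randomAffinity(8)
    W@.Data[W@.Data == 0] <- 0.05; diag(W@.Data) <- 0
    for (prob in c("standard", "generalized")) {
      s <- runif(1, 0.01, 100)
      expect_equal(vbIndex(affinityMatrix(s * W@.Data), prob),
                   vbIndex(W, prob), tolerance = 1e-8)
    }
  }
})

test_that("vbIndex stays in [0,1] on random affinities", {
  set.seed(32)
  for (i in 1:50) {
    W <- randomAffinity(sample(4:10, 1))
    W@.Data[W@.Data == 0] <- 0.02; diag(W@.Data) <- 0
    v <- vbIndex(W)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("vbIndex rises monotonically as a two-block graph reconnects", {
  blockW <- function(cross) {
    W <- matrix(cross, 8, 8)
    W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
    affinityMatrix(W)
  }
  vals <- sapply(seq(0, 1, by = 0.1), function(c)
    suppressWarnings(vbIndex(blockW(c), "generalized",
                             isolated = "drop")))
  expect_equal(vals[1], 0, tolerance = 1e-10)  # disconnected
  expect_equal(vals[11], 1, tolerance = 1e-10) # uniform
  expect_true(all(diff(vals) > 0))
})

test_that("isolated nodes: error by default, 0 (a complete split) on drop", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- W[1, 3] <- W[3, 1] <- 1
  expect_error(vbIndex(affinityMatrix(W), "generalized"), "isolated")
  expect_equal(vbIndex(affinityMatrix(W), "generalized", isolated = "drop"),
               0)
  expect_warning(v0 <- vbIndex(affinityMatrix(matrix(0, 4, 4))), "zero")
  expect_equal(v0, 0)
})

test_that("fullAnalysis: piecewise-constant parcels and uniform features", {
  # 6 parcels of identical series -> Fiedler has 6 distinct values
  f <- groupedFeatures(c(5, 4, 6, 5, 4, 6), T = 60, seed = 41)
  res <- fullAnalysis(f, d = 3)
  fv <- gradientCoords(vbGradient(res))[, 1]
  expect_equal(length(unique(round(fv, 6))), 6L)
  expect_s4_class(vbGradient(res), "GradientMap")

  # all nodes identical -> uniform affinity -> vb = 1
  f1 <- groupedFeatures(6, T = 30, seed = 42)
  expect_equal(vbValues(fullAnalysis(f1, d = 1)), 1, tolerance = 1e-10)
})

test_that("orthogonal-feature halves disconnect under zero_negatives: vb near 0", {
  f <- orthogonalGroups(4, T = 60)
  res <- suppressWarnings(
    fullAnalysis(f, problem = "generalized", d = 1, isolated = "drop"))
  expect_lt(vbValues(res), 1e-6)
})

test_that("clusteredAnalysis reduces to fullAnalysis for a single cluster", {
  set.seed(43)
  f <- matrix(rnorm(9 * 50), 9)
  res <- clusteredAnalysis(f, rep(1L, 9), d = 2)
  full <- fullAnalysis(f, d = 2)
  expect_equal(unname(vbValues(res)["1"]), vbValues(full), tolerance = 1e-12)
  expect_equal(gradientCoords(vbGradient(res)[["1"]]),
               gradientCoords(vbGradient(full)))
})

test_that("clusteredAnalysis: true parcels score 1; tiny clusters go missing", {
  f <- groupedFeatures(c(4, 5, 6), T = 40, seed = 44)
  labels <- rep(1:3, c(4, 5, 6))
  res <- clusteredAnalysis(f, labels)
  expect_equal(unname(vbValues(res)), rep(1, 3), tolerance = 1e-10)

  labels2 <- c(rep(1L, 4), rep(2L, 5), rep(3L, 4), 4L, 4L)
  expect_warning(res2 <- clusteredAnalysis(f, labels2), "< 3 members")
  expect_true(is.na(vbValues(res2)["4"]))
  exp <- expandToVertices(res2, labels2)
  expect_equal(length(exp), 15L)
  expect_true(all(is.na(exp[14:15])))
})

test_that("searchlight on an icosphere: interior 1, parcel borders lower", {
  mesh <- makeIcosphere(2)                      # 162 vertices
  labels <- parcellateMesh(mesh, 4, seed = 7)
  f <- parcelTimeseries(labels, 60, crossCorr = 0.3, noiseSd = 0, seed = 7)
  res <- searchlightAnalysis(f, mesh)
  v <- vbValues(res)
  ring <- oneRing(mesh)
  boundary <- sapply(seq_len(nVertices(mesh)), function(i)
    any(labels[ring[[i]]] != labels[i]))
  # edge-detection contract: vb < 1 exactly at vertices with a cross-parcel
  # neighbour
  expect_true(all(abs(v[!boundary] - 1) < 1e-6))
  expect_true(all(v[boundary] < 1 - 1e-6))
  expect_true(all(res@neighborhoodSizes %in% c(6L, 7L)))
})

test_that("searchlight respects masks and flags too-small neighbourhoods", {
  mesh <- makeIcosphere(1)                      # 42 vertices
  set.seed(45)
  f <- matrix(rnorm(42 * 30), 42)
  mask <- rep(TRUE, 42); mask[1:2] <- FALSE
  res <- searchlightAnalysis(f, mesh, mask)
  v <- vbValues(res)
  expect_true(all(is.na(v[1:2])))
  expect_true(all(!is.na(v[3:42])))
  # masking a vertex's whole neighbourhood but 2 -> NA at that vertex
  ring <- oneRing(mesh)
  mask2 <- rep(FALSE, 42)
  mask2[c(10, ring[[10]][1:2])] <- TRUE
  res2 <- searchlightAnalysis(f, mesh, mask2)
  keepn <- c(10, ring[[10]][1:2])
  expect_true(sum(!is.na(vbValues(res2))) <= 3)
})

test_that("searchlight neighbourhood spanning orthogonal parcels scores ~0", {
  mesh <- makeIcosphere(1)
  n <- nVertices(mesh)
  ring <- oneRing(mesh)
  centre <- 13L                                  # a 6-neighbour vertex
  split <- c(centre, ring[[centre]])
  sideA <- split[1:3]; sideB <- split[4:length(split)]
  Q <- qr.Q(qr(scale(matrix(rnorm(80), 40), scale = FALSE)))
  f <- matrix(rnorm(n * 40), n)
  f[sideA, ] <- matrix(Q[, 1], length(sideA), 40, byrow = TRUE)
  f[sideB, ] <- matrix(Q[, 2], length(sideB), 40, byrow = TRUE)
  res <- searchlightAnalysis(f, mesh)
  expect_lt(vbValues(res)[centre], 1e-6)
})

test_that("parallel searchlight equals the serial reference", {
  mesh <- makeIcosphere(1)
  labels <- parcellateMesh(mesh, 3, seed = 5)
  f <- parcelTimeseries(labels, 40, noiseSd = 0.2, seed = 5)
  r1 <- searchlightAnalysis(f, mesh, jobs = 1)
  r4 <- searchlightAnalysis(f, mesh, jobs = 4)
  expect_identical(vbValues(r1), vbValues(r4))
})
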