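makeVolume <- function(a, voxelSize = 1, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  new("GrayMatterVolume", intensities = a, voxelSize = rep(voxelSize, 3),
      affine = diag(c(rep(voxelSize, 3), 1)), mask = mask)
}

test_that("cube extraction tiles the grid in scan order", {
  a <- array(seq_len(27) / 27, c(3, 3, 3))
  cb <- extractCubes(makeVolume(a))
  expect_identical(nNodes(cb), 1L)
  expect_equal(cubeValues(cb)[1, ], as.numeric(a))
  b <- array(runif(6^3) + 0.1, c(6, 6, 6))
  cb6 <- extractCubes(makeVolume(b))
  expect_identical(nNodes(cb6), 8L)
  # lexicographic grid order and grid alignment
  expect_identical(gridIndex(cb6)[1, ], c(0L, 0L, 0L))
  expect_identical(gridIndex(cb6)[2, ], c(0L, 0L, 1L))
  expect_identical(gridIndex(cb6)[8, ], c(1L, 1L, 1L))
  expect_equal(cubeValues(cb6)[8, ], as.numeric(b[4:6, 4:6, 4:6]))
})

test_that("ellipsoid-masked node count matches an exhaustive scan", {
  v <- simulateVolume(shape = c(30, 30, 30), seed = 4)
  cb <- extractCubes(v, inclusionThreshold = 1)
  inb <- brainMask(v) & intensities(v) > 0
  cnt <- 0
  for (a in 0:9) for (b in 0:9) for (cc in 0:9)
    if (all(inb[3 * a + 1:3, 3 * b + 1:3, 3 * cc + 1:3])) cnt <- cnt + 1
  expect_identical(nNodes(cb), as.integer(cnt))
})

test_that("extraction errors when no cube passes inclusion", {
  a <- array(0, c(9, 9, 9))
  expect_error(extractCubes(makeVolume(a)), "empty network")
})

test_that("the lattice transform set is the 48-element cube group", {
  tr <- symmetryTransforms()
  expect_length(tr, 48)
  expect_identical(tr[[1]], 1:27)               # identity first
  keys <- vapply(tr, paste, character(1), collapse = ",")
  expect_identical(anyDuplicated(keys), 0L)
  # closed under composition and inversion
  compose <- function(p, q) q[p]
  v <- rnorm(27)
  for (i in c(2, 17, 48)) {
    for (j in c(3, 25)) {
      expect_true(paste(compose(tr[[i]], tr[[j]]), collapse = ",") %in%
                    keys)
    }
    inv <- order(tr[[i]])
    expect_true(paste(inv, collapse = ",") %in% keys)
    expect_equal(v[tr[[i]]][inv], v)
  }
  # matches the independently generated group
  okeys <- vapply(oracleTransforms(), paste, character(1), collapse = ",")
  expect_setequal(keys, okeys)
})

test_that("interpolated 45-degree dialect contains the axis rotations", {
  tr <- symmetryTransforms("interp45")
  expect_gt(length(tr), 48)
  expect_equal(tr[[1]], diag(27), tolerance = 1e-9)
  # every weight matrix maps constant vectors to constant vectors
  for (W in tr[c(2, 10, length(tr))])
    expect_equal(as.numeric(W %*% rep(1, 27)), rep(1, 27),
                 tolerance = 1e-6)
})

test_that("maximum rotated similarity attains 1 for congruent cubes", {
  set.seed(1)
  a <- rnorm(27)
  expect_equal(maxRotatedSimilarity(a, a), 1)
  mirror <- symmetryTransforms()[[2]]
  expect_equal(maxRotatedSimilarity(a, a[mirror]), 1)
  expect_equal(maxRotatedSimilarity(a, rev(a)), 1)
})

test_that("maximum rotated similarity matches the exhaustive oracle", {
  perms <- oracleTransforms()
  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(27)
    b <- rnorm(27)
    expect_equal(maxRotatedSimilarity(a, b), oracleMaxRot(a, b, perms),
                 tolerance = 1e-12)
    # never below the plain correlation, symmetric in its arguments
    expect_gte(maxRotatedSimilarity(a, b), cor(a, b) - 1e-12)
    expect_equal(maxRotatedSimilarity(a, b), maxRotatedSimilarity(b, a),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance cubes get similarity 0 and a flag", {
  s <- maxRotatedSimilarity(rep(1, 27), rnorm(27))
  expect_identical(as.numeric(s), 0)
  expect_true(attr(s, "zeroVariance"))
})

test_that("the similarity matrix equals entrywise oracle recomputation", {
  set.seed(3)
  V <- matrix(rnorm(12 * 27), 12, 27)
  cb <- new("CubeSet", values = V,
            gridIndex = matrix(0L, 12, 3),
            worldCenter = matrix(0, 12, 3),
            zeroVariance = rep(FALSE, 12))
  S <- simValues(buildSimilarityMatrix(cb))
  perms <- oracleTransforms()
  for (i in 1:11) for (j in (i + 1):12)
    expect_equal(S[i, j], oracleMaxRot(V[i, ], V[j, ], perms),
                 tolerance = 1e-10)
  expect_lt(max(abs(S - t(S))), 1e-12)
  expect_true(all(S >= -1 & S <= 1))
})

test_that("permuting node order permutes the similarity matrix", {
  set.seed(4)
  V <- matrix(rnorm(8 * 27), 8, 27)
  mk <- function(V) new("CubeSet", values = V,
                        gridIndex = matrix(0L, nrow(V), 3),
                        worldCenter = matrix(0, nrow(V), 3),
                        zeroVariance = rep(FALSE, nrow(V)))
  S1 <- simValues(buildSimilarityMatrix(mk(V)))
  p <- c(5, 3, 8, 1, 2, 7, 4, 6)
  S2 <- simValues(buildSimilarityMatrix(mk(V[p, ])))
  expect_equal(S2, S1[p, p], tolerance = 1e-12)
})

test_that("identical nodes are maximally similar in the matrix", {
  V <- matrix(rnorm(27), 2, 27, byrow = TRUE)
  cb <- new("CubeSet", values = V, gridIndex = matrix(0L, 2, 3),
            worldCenter = matrix(0, 2, 3), zeroVariance = c(FALSE, FALSE))
  expect_equal(simValues(buildSimilarityMatrix(cb))[1, 2], 1)
})

test_that("t-mode binarization handles the degenerate extremes", {
  n <- 10
  S <- matrix(0.99, n, n)
  net <- fdrBinarize(simFromMatrix(S), q = 0.05, nullMethod = "t")
  expect_identical(nEdges(net), as.integer(n * (n - 1) / 2))
  S0 <- matrix(0, n, n)
  net0 <- fdrBinarize(simFromMatrix(S0), q = 0.05, nullMethod = "t")
  expect_identical(nEdges(net0), 0L)
  expect_identical(rThreshold(net0), Inf)
})

test_that("t-mode edge sets equal the step-by-step BH oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 15
    S <- matrix(0, n, n)
    S[upper.tri(S)] <- runif(n * (n - 1) / 2, -0.3, 0.9)
    S <- S + t(S)
    sim <- simFromMatrix(S)
    net <- fdrBinarize(sim, q = 0.05, nullMethod = "t")
    r <- S[upper.tri(S)]
    df <- 25
    p <- pt(r * sqrt(df / (1 - r^2)), df, lower.tail = FALSE)
    rej <- oracleBH(p, 0.05)
    got <- which(adjacency(net)[upper.tri(S)] != 0)
    expect_identical(got, rej)
  }
})

test_that("binarization is monotone in q and has a scalar cutoff", {
  set.seed(6)
  n <- 20
  S <- matrix(0, n, n)
  S[upper.tri(S)] <- runif(n * (n - 1) / 2, 0, 0.95)
  S <- S + t(S)
  sim <- simFromMatrix(S)
  prev <- 0L
  for (q in c(0.01, 0.05, 0.2, 0.5)) {
    net <- fdrBinarize(sim, q = q, nullMethod = "t")
    expect_gte(nEdges(net), prev)
    prev <- nEdges(net)
    r <- S[upper.tri(S)]
    kept <- adjacency(net)[upper.tri(S)] != 0
    if (any(kept) && any(!kept))
      expect_gt(min(r[kept]), max(r[!kept]))
    expect_gte(min(r[kept]), rThreshold(net))
  }
  expect_error(fdrBinarize(sim, q = 1.2), "\\(0, 1\\)")
})

test_that("scramble-null binarization is deterministic and needs cubes", {
  v <- simulateVolume(shape = c(15, 15, 15), seed = 2, fwhm = 8)
  cb <- extractCubes(v)
  sim <- buildSimilarityMatrix(cb)
  expect_error(fdrBinarize(sim), "cubes")
  n1 <- fdrBinarize(sim, cubes = cb, seed = 10)
  n2 <- fdrBinarize(sim, cubes = cb, seed = 10)
  expect_identical(as.matrix(adjacency(n1)), as.matrix(adjacency(n2)))
  expect_identical(Matrix::diag(adjacency(n1)), rep(0, nNodes(n1)))
  expect_identical(
    nEdges(n1), as.integer(sum(adjacency(n1)) / 2))
})

test_that("a fixed threshold and the pooled threshold binarize consistently", {
  set.seed(7)
  n <- 12
  S <- matrix(0, n, n)
  S[upper.tri(S)] <- runif(n * (n - 1) / 2, 0, 0.9)
  S <- S + t(S)
  sim <- simFromMatrix(S)
  net <- fdrBinarize(sim, rThreshold = 0.6)
  r <- S[upper.tri(S)]
  expect_identical(which(adjacency(net)[upper.tri(S)] != 0),
                   which(r >= 0.6))
  thr <- pooledFDRThreshold(list(sim, sim), q = 0.05, nullMethod = "t")
  single <- fdrBinarize(sim, q = 0.05, nullMethod = "t")
  expect_identical(nEdges(fdrBinarize(sim, rThreshold = thr)),
                   nEdges(single))
})
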