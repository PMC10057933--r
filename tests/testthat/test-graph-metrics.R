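completeNetwork <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  new("BinaryNetwork",
      adjacency = as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
      rThreshold = NA_real_, qValue = NA_real_)
}

starNetwork <- function(n) {
  A <- matrix(0, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1
  new("BinaryNetwork",
      adjacency = as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
      rThreshold = NA_real_, qValue = NA_real_)
}

cycleNetwork <- function(n) ringLattice(n, 2)

test_that("clustering is 1 on complete graphs and 0 on stars", {
  k4 <- clusteringCoefficient(completeNetwork(4))
  expect_equal(k4$perNode, rep(1, 4))
  expect_equal(k4$mean, 1)
  s5 <- clusteringCoefficient(starNetwork(5))
  expect_equal(s5$mean, 0)
})

test_that("clustering matches the brute-force triangle oracle", {
  for (s in 1:10) {
    net <- randomNetwork(30, 0.2, seed = s)
    got <- clusteringCoefficient(net)
    expect_equal(got$perNode, oracleClustering(adjacency(net)),
                 tolerance = 1e-12)
  }
})

test_that("path length has its closed-form values on K_n and C_5", {
  expect_equal(characteristicPathLength(completeNetwork(7))$L, 1)
  expect_equal(characteristicPathLength(cycleNetwork(5))$L, 1.5)
})

test_that("path length matches the all-pairs BFS oracle", {
  for (s in 1:10) {
    net <- randomNetwork(25, 0.1, seed = 100 + s)
    if (nEdges(net) == 0) next
    got <- characteristicPathLength(net)
    expect_equal(got$L, oraclePathLength(adjacency(net)),
                 tolerance = 1e-12)
  }
})

test_that("path length is undefined for edgeless networks", {
  A <- matrix(0, 4, 4)
  net <- new("BinaryNetwork",
             adjacency = as(Matrix::Matrix(A, sparse = TRUE),
                            "generalMatrix"),
             rThreshold = NA_real_, qValue = NA_real_)
  expect_error(characteristicPathLength(net), "no edges")
})

test_that("harmonic path length tolerates disconnected graphs", {
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  net <- new("BinaryNetwork",
             adjacency = as(Matrix::Matrix(A, sparse = TRUE),
                            "generalMatrix"),
             rThreshold = NA_real_, qValue = NA_real_)
  res <- characteristicPathLength(net, method = "harmonic")
  expect_equal(res$L, 1 / (2 / 10))   # 2 reachable pairs of 10
})

test_that("rewiring preserves the degree sequence and edge count", {
  for (s in 1:5) {
    net <- randomNetwork(40, 0.15, seed = 200 + s)
    rn <- randomizeNetwork(net, seed = s)
    expect_identical(Matrix::rowSums(adjacency(rn)),
                     Matrix::rowSums(adjacency(net)))
    expect_identical(nEdges(rn), nEdges(net))
    expect_identical(Matrix::diag(adjacency(rn)), rep(0, 40))
  }
})

test_that("rewiring is deterministic given the seed", {
  net <- randomNetwork(30, 0.2, seed = 1)
  r1 <- randomizeNetwork(net, seed = 9)
  r2 <- randomizeNetwork(net, seed = 9)
  expect_identical(as.matrix(adjacency(r1)), as.matrix(adjacency(r2)))
  r3 <- randomizeNetwork(net, seed = 10)
  expect_false(identical(as.matrix(adjacency(r1)),
                         as.matrix(adjacency(r3))))
})

test_that("tiny networks are returned unchanged with a warning", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  net <- new("BinaryNetwork",
             adjacency = as(Matrix::Matrix(A, sparse = TRUE),
                            "generalMatrix"),
             rThreshold = NA_real_, qValue = NA_real_)
  expect_warning(rn <- randomizeNetwork(net, seed = 1), "too small")
  expect_identical(as.matrix(adjacency(rn)), as.matrix(adjacency(net)))
})

test_that("rewiring destroys lattice clustering", {
  net <- ringLattice(100, 4)
  c0 <- clusteringCoefficient(net)$mean
  hits <- sum(vapply(1:20, function(s)
    clusteringCoefficient(randomizeNetwork(net, seed = s))$mean < c0,
    logical(1)))
  expect_gte(hits, 20 * 0.95)
})

test_that("sigma equals gamma over lambda exactly", {
  net <- randomNetwork(60, 0.15, seed = 3)
  p <- smallWorldProperties(net, nRandom = 3, seed = 1)
  expect_identical(smallWorldCoef(p), normClustering(p) / normPathLength(p))
  df <- as.data.frame(p)
  expect_named(df, c("C", "L", "C_rand", "L_rand", "gamma", "lambda",
                     "sigma", "n_random", "component_fraction"))
})

test_that("a ring lattice is strongly small-world", {
  net <- ringLattice(100, 4)
  gs <- vapply(1:3, function(s)
    normClustering(smallWorldProperties(net, nRandom = 5, seed = s)),
    numeric(1))
  expect_gt(min(gs), 2)
})

test_that("metrics are invariant under node relabeling", {
  net <- randomNetwork(40, 0.2, seed = 17)
  A <- as.matrix(adjacency(net))
  p <- withr::with_seed(5, sample(40))
  netP <- new("BinaryNetwork",
              adjacency = as(Matrix::Matrix(A[p, p], sparse = TRUE),
                             "generalMatrix"),
              rThreshold = NA_real_, qValue = NA_real_)
  expect_equal(clusteringCoefficient(netP)$mean,
               clusteringCoefficient(net)$mean, tolerance = 1e-12)
  expect_equal(characteristicPathLength(netP)$L,
               characteristicPathLength(net)$L, tolerance = 1e-12)
})

test_that("a fragmented network triggers the component warning", {
  A <- matrix(0, 17, 17)
  ring <- as.matrix(adjacency(ringLattice(15, 4)))
  A[1:15, 1:15] <- ring
  A[16, 17] <- A[17, 16] <- 1            # detached pair: 15/17 < 90%
  net <- new("BinaryNetwork",
             adjacency = as(Matrix::Matrix(A, sparse = TRUE),
                            "generalMatrix"),
             rThreshold = NA_real_, qValue = NA_real_)
  expect_warning(smallWorldProperties(net, nRandom = 1, seed = 1),
                 "component")
})

test_that("an all-degree-one network has a degenerate random reference", {
  A <- matrix(0, 12, 12)
  for (i in seq(1, 11, 2)) A[i, i + 1] <- A[i + 1, i] <- 1
  net <- new("BinaryNetwork",
             adjacency = as(Matrix::Matrix(A, sparse = TRUE),
                            "generalMatrix"),
             rThreshold = NA_real_, qValue = NA_real_)
  expect_error(suppressWarnings(
    smallWorldProperties(net, nRandom = 2, seed = 1)),
    "degenerate")
})
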