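# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive algorithms and code paths different from
# the package internals.

# All 48 cube symmetries, built by closing the generator set (three 90
# degree rotations + one reflection) under composition. Returns a list
# of permutations of 1:27 (value at i comes from position p[i]).
oracleTransforms <- function() {
  co <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  key <- function(m) (m[, 1] + 1) + 3 * (m[, 2] + 1) + 9 * (m[, 3] + 1)
  k0 <- key(co)
  permOf <- function(M) match(key(co %*% M), k0)  # source positions
  rx <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, byrow = TRUE)
  ry <- matrix(c(0, 0, 1, 0, 1, 0, -1, 0, 0), 3, byrow = TRUE)
  rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  fx <- diag(c(-1, 1, 1))
  mats <- list(diag(3))
  keys <- paste(permOf(diag(3)), collapse = ",")
  frontier <- mats
  while (length(frontier)) {
    nxt <- list()
    for (M in frontier) for (G in list(rx, ry, rz, fx)) {
      Mn <- M %*% G
      kk <- paste(permOf(Mn), collapse = ",")
      if (!kk %in% keys) {
        keys <- c(keys, kk)
        mats <- c(mats, list(Mn))
        nxt <- c(nxt, list(Mn))
      }
    }
    frontier <- nxt
  }
  lapply(mats, permOf)
}

oracleMaxRot <- function(a, b, perms = oracleTransforms()) {
  max(vapply(perms, function(p) cor(a, b[p]), numeric(1)))
}

# per-node clustering by explicit neighbor-pair triangle counting
oracleClustering <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    t <- 0
    for (u in seq_len(k - 1)) for (v in (u + 1):k)
      if (A[nb[u], nb[v]] != 0) t <- t + 1
    2 * t / (k * (k - 1))
  }, numeric(1))
}

# all-pairs BFS distances; Inf where unreachable
oracleDistances <- function(A) {
  A <- as.matrix(A) != 0
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in which(A[u, ])) if (!is.finite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
    D[s, ] <- dist
  }
  D
}

# mean shortest path over ordered pairs within the largest component
oraclePathLength <- function(A) {
  D <- oracleDistances(A)
  n <- nrow(D)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (s in seq_len(n)) if (is.na(comp[s])) {
    cid <- cid + 1
    comp[is.finite(D[s, ])] <- cid
  }
  big <- which(comp == which.max(tabulate(comp)))
  sub <- D[big, big, drop = FALSE]
  mean(sub[row(sub) != col(sub)])
}

# step-by-step Benjamini-Hochberg: indices of rejected hypotheses
oracleBH <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  if (!length(k)) return(integer(0))
  sort(ord[seq_len(max(k))])
}

# partial correlation via explicit normal-equation residuals
oraclePartialCor <- function(x, y, Z) {
  Z1 <- cbind(1, as.matrix(Z))
  bx <- solve(t(Z1) %*% Z1, t(Z1) %*% x)
  by <- solve(t(Z1) %*% Z1, t(Z1) %*% y)
  cor(x - Z1 %*% bx, y - Z1 %*% by)
}

# random BinaryNetwork (Erdos-Renyi) for property tests
randomNetwork <- function(n, p, seed) {
  A <- withr::with_seed(seed, {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < p)
    A + t(A)
  })
  new("BinaryNetwork",
      adjacency = as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
      rThreshold = NA_real_, qValue = NA_real_)
}

# similarity matrix object from a raw symmetric matrix
simFromMatrix <- function(S) {
  diag(S) <- 1
  new("SimilarityMatrix", values = S, zeroVariance = rep(FALSE, nrow(S)))
}

# ring lattice where each node connects to its k nearest neighbours
ringLattice <- function(n, k) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i - 1 + d) %% n) + 1
    A[i, j] <- A[j, i] <- 1
  }
  new("BinaryNetwork",
      adjacency = as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
      rThreshold = NA_real_, qValue = NA_real_)
}
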