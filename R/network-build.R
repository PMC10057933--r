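# Single-subject similarity network construction: cube parcellation,
# symmetry-maximized correlation, FDR binarization.

# ---- Cube extraction ---------------------------------------------------

#' Extract 3x3x3-voxel cube nodes from a volume
#'
#' Tiles the volume with non-overlapping 3x3x3-voxel cubes anchored at the
#' grid origin. A cube is retained as a network node when the fraction of
#' its 27 voxels that are inside the brain mask with positive intensity is
#' at least \code{inclusionThreshold} (default 1: fully in-brain cubes
#' only). Nodes are ordered lexicographically by grid index so the node
#' set and all downstream outputs are reproducible bit for bit.
#'
#' @param volume a \linkS4class{GrayMatterVolume} with each dimension >= 3.
#' @param inclusionThreshold required in-mask fraction in [0, 1].
#' @return a \linkS4class{CubeSet}.
#' @examples
#' v <- simulateVolume(shape = c(12, 12, 12), seed = 1)
#' extractCubes(v)
#' @export
extractCubes <- function(volume, inclusionThreshold = 1) {
  stopifnot(is(volume, "GrayMatterVolume"))
  if (inclusionThreshold < 0 || inclusionThreshold > 1)
    stop("'inclusionThreshold' must lie in [0, 1]")
  d <- dim(volume@intensities)
  if (any(d < 3L)) stop("volume dimensions must each be >= 3 voxels")
  nc <- d %/% 3L
  grid <- as.matrix(expand.grid(a = 0:(nc[1] - 1L), b = 0:(nc[2] - 1L),
                                c = 0:(nc[3] - 1L)))
  # lexicographic order on (a, b, c): third index slowest in expand.grid
  # gives (a fastest); reorder so a is the major key
  grid <- grid[order(grid[, 1], grid[, 2], grid[, 3]), , drop = FALSE]
  vals <- matrix(NA_real_, nrow(grid), 27L)
  frac <- numeric(nrow(grid))
  gm <- volume@intensities
  inb <- volume@mask & gm > 0
  for (i in seq_len(nrow(grid))) {
    ix <- (3L * grid[i, 1] + 1L):(3L * grid[i, 1] + 3L)
    iy <- (3L * grid[i, 2] + 1L):(3L * grid[i, 2] + 3L)
    iz <- (3L * grid[i, 3] + 1L):(3L * grid[i, 3] + 3L)
    vals[i, ] <- as.numeric(gm[ix, iy, iz])
    frac[i] <- mean(inb[ix, iy, iz])
  }
  keep <- frac >= inclusionThreshold
  if (!any(keep))
    stop("empty network: no cube reaches the inclusion threshold")
  grid <- grid[keep, , drop = FALSE]
  vals <- vals[keep, , drop = FALSE]
  # world coordinates of cube centers (0-based center voxel 3a+1)
  ctrVox <- cbind(3 * grid[, 1] + 1, 3 * grid[, 2] + 1, 3 * grid[, 3] + 1)
  world <- t(volume@affine %*% t(cbind(ctrVox, 1)))[, 1:3, drop = FALSE]
  sds <- apply(vals, 1, sd)
  new("CubeSet", values = vals,
      gridIndex = matrix(as.integer(grid), ncol = 3L),
      worldCenter = world, zeroVariance = sds < 1e-12)
}

# ---- Cube symmetry transforms ------------------------------------------

# coordinates of the 27 cube positions in array scan order, in {-1,0,1}^3
cubeCoords <- function() {
  as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
}

latticeSymmetryPerms <- function() {
  co <- cubeCoords()
  key <- function(m) apply(m + 1, 1, function(r) r[1] + 3 * r[2] + 9 * r[3])
  k0 <- key(co)
  perms <- list()
  axesPerms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                    c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(s1 = c(1, -1), s2 = c(1, -1),
                                 s3 = c(1, -1)))
  for (ap in axesPerms) for (si in seq_len(nrow(signs))) {
    M <- matrix(0, 3, 3)
    for (r in 1:3) M[r, ap[r]] <- signs[si, r]
    # value at target position y comes from source position M^{-1} y;
    # for signed permutation matrices the inverse is the transpose
    src <- co %*% M                     # (M^T y)^T rows = y^T M
    p <- match(key(src), k0)
    perms[[length(perms) + 1L]] <- as.integer(p)
  }
  perms <- unique(perms)
  idt <- which(vapply(perms, function(p) all(p == 1:27), logical(1)))
  c(perms[idt], perms[-idt])
}

rotMat <- function(axis, theta) {
  c0 <- cos(theta); s0 <- sin(theta)
  switch(axis,
    matrix(c(1, 0, 0, 0, c0, -s0, 0, s0, c0), 3, byrow = TRUE),
    matrix(c(c0, 0, s0, 0, 1, 0, -s0, 0, c0), 3, byrow = TRUE),
    matrix(c(c0, -s0, 0, s0, c0, 0, 0, 0, 1), 3, byrow = TRUE))
}

# trilinear interpolation weights of one source point over the 27 lattice
# positions (coordinates clamped into the cube)
trilinearWeights <- function(p) {
  p <- pmin(pmax(p, -1), 1)
  w <- numeric(27)
  lo <- floor(p); lo <- pmin(lo, 0)      # cell lower corner in {-1, 0}
  fr <- p - lo
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    cx <- lo[1] + dx; cy <- lo[2] + dy; cz <- lo[3] + dz
    wt <- (if (dx) fr[1] else 1 - fr[1]) *
          (if (dy) fr[2] else 1 - fr[2]) *
          (if (dz) fr[3] else 1 - fr[3])
    if (wt > 0) {
      idx <- (cx + 1) + 3 * (cy + 1) + 9 * (cz + 1) + 1
      w[idx] <- w[idx] + wt
    }
  }
  w
}

interp45Transforms <- function() {
  co <- cubeCoords()
  mats <- list()
  signs <- as.matrix(expand.grid(s1 = c(1, -1), s2 = c(1, -1),
                                 s3 = c(1, -1)))
  for (axis in 1:3) for (k in 0:7) for (si in seq_len(nrow(signs))) {
    # inverse of an orthogonal map is its transpose
    Minv <- t(rotMat(axis, k * pi / 4) %*% diag(signs[si, ]))
    W <- matrix(0, 27, 27)
    for (i in 1:27) W[i, ] <- trilinearWeights(as.numeric(Minv %*% co[i, ]))
    mats[[length(mats) + 1L]] <- round(W, 10)
  }
  mats <- unique(mats)
  idt <- which(vapply(mats, function(W) all(abs(W - diag(27)) < 1e-9),
                      logical(1)))
  c(mats[idt], mats[-idt])
}

transformCache <- new.env(parent = emptyenv())

#' Cube symmetry transform set
#'
#' Returns the set of cube transforms over which similarity is maximized.
#' The default \code{"lattice48"} dialect is the full symmetry group of
#' the cube realized exactly on the 3x3x3 lattice: all 48 combinations of
#' axis permutations and axis reflections (24 proper rotations and their
#' mirror images), each represented as a permutation of the 27 voxel
#' positions. The set contains the identity (element 1) and is closed
#' under composition and inversion, which makes the maximized similarity
#' symmetric in its two arguments.
#'
#' The \code{"interp45"} dialect additionally realizes rotations in 45
#' degree steps about each coordinate axis (combined with reflections) via
#' trilinear interpolation at the lattice points, with coordinates clamped
#' to the cube; these transforms are approximate and not invertible, and
#' are provided as an alternative reading of "rotations by multiples of
#' 45 degrees". Each element is then a 27x27 weight matrix.
#'
#' @param dialect \code{"lattice48"} (default) or \code{"interp45"}.
#' @return for \code{"lattice48"}, a list of 48 integer permutations of
#'   1:27 (transformed values are \code{v[perm]}); for \code{"interp45"},
#'   a list of 27x27 weight matrices. The dialect is recorded in the
#'   \code{"dialect"} attribute.
#' @examples
#' length(symmetryTransforms())
#' @export
symmetryTransforms <- function(dialect = c("lattice48", "interp45")) {
  dialect <- match.arg(dialect)
  if (is.null(transformCache[[dialect]])) {
    transformCache[[dialect]] <- switch(dialect,
      lattice48 = latticeSymmetryPerms(),
      interp45 = interp45Transforms())
  }
  structure(transformCache[[dialect]], dialect = dialect)
}

applyCubeTransform <- function(v, tr) {
  if (is.matrix(tr)) as.numeric(tr %*% v) else v[tr]
}

# ---- Maximum rotated similarity ----------------------------------------

#' Maximum rotated similarity between two cubes
#'
#' The similarity of two cube nodes is the largest Pearson correlation
#' between the 27 intensities of the first cube and any symmetry
#' transform of the second, accommodating differing local orientation of
#' cortical folds. When either cube has zero intensity variance the
#' correlation is undefined and the similarity is defined as 0, flagged
#' via the \code{"zeroVariance"} attribute.
#'
#' @param a,b numeric vectors of length 27 (cube intensities in scan
#'   order).
#' @param transforms a transform set from [symmetryTransforms()].
#' @return the maximum correlation, in [-1, 1].
#' @examples
#' v <- rnorm(27)
#' maxRotatedSimilarity(v, rev(v))  # reflections are in the set: 1
#' @export
maxRotatedSimilarity <- function(a, b, transforms = symmetryTransforms()) {
  stopifnot(length(a) == 27L, length(b) == 27L)
  if (sd(a) < 1e-12 || sd(b) < 1e-12)
    return(structure(0, zeroVariance = TRUE))
  best <- -1
  for (tr in transforms) {
    tb <- applyCubeTransform(b, tr)
    if (sd(tb) < 1e-12) next
    best <- max(best, cor(a, tb))
  }
  min(max(best, -1), 1)
}

#' Build the similarity matrix over all cube pairs
#'
#' Evaluates [maxRotatedSimilarity()] for every unordered node pair. With
#' the lattice dialect this is fully vectorized: rows are standardized
#' once and, for each of the 48 permutations, one matrix product yields
#' all pairwise correlations; the entrywise maximum over transforms is
#' the similarity matrix. Because the transform set is closed under
#' inversion the result is symmetric; it is symmetrized by the entrywise
#' maximum with its transpose to remove floating-point asymmetry.
#' Zero-variance nodes get similarity 0 against every other node and are
#' flagged.
#'
#' @param cubes a \linkS4class{CubeSet} (>= 2 nodes).
#' @param transforms transform set from [symmetryTransforms()].
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
buildSimilarityMatrix <- function(cubes,
                                  transforms = symmetryTransforms()) {
  stopifnot(is(cubes, "CubeSet"))
  V <- cubes@values
  n <- nrow(V)
  if (n < 2L) stop("at least 2 nodes are required")
  zv <- cubes@zeroVariance
  ctr <- V - rowMeans(V)
  ss <- sqrt(rowSums(ctr^2))
  ss[ss < 1e-12] <- Inf                  # zero-variance rows -> zero vector
  Z <- ctr / ss
  dialect <- attr(transforms, "dialect")
  S <- matrix(-1, n, n)
  if (identical(dialect, "interp45")) {
    for (tr in transforms) {
      Vt <- V %*% t(tr)
      ct <- Vt - rowMeans(Vt)
      st <- sqrt(rowSums(ct^2))
      st[st < 1e-12] <- Inf
      Zt <- ct / st
      S <- pmax(S, Z %*% t(Zt))
    }
  } else {
    for (tr in transforms) S <- pmax(S, Z %*% t(Z[, tr, drop = FALSE]))
  }
  S <- pmax(S, t(S))
  S[zv, ] <- 0
  S[, zv] <- 0
  S <- pmin(pmax(S, -1), 1)
  diag(S) <- 1
  new("SimilarityMatrix", values = S, zeroVariance = zv)
}

# ---- FDR binarization --------------------------------------------------

# one-sided p-value of a positive correlation via the t transform
corPValue <- function(r, df) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  t[r >= 1] <- Inf
  t[r <= -1] <- -Inf
  pt(t, df, lower.tail = FALSE)
}

# Monte-Carlo null of the maximum rotated similarity under "chance"
# pairing: cube contents are scrambled (within-cube voxel permutation),
# destroying spatial pattern while keeping marginals, then the rotation-
# maximized correlation is computed for random scrambled pairs. Returns
# mean and sd on the Fisher-z scale.
scrambleNullMoments <- function(values, transforms, nNull, seed) {
  n <- nrow(values)
  withSeed(seed, {
    i1 <- sample.int(n, nNull, replace = TRUE)
    i2 <- sample.int(n, nNull, replace = TRUE)
    A <- t(vapply(i1, function(i) sample(values[i, ]), numeric(27)))
    B <- t(vapply(i2, function(i) sample(values[i, ]), numeric(27)))
    za <- A - rowMeans(A); zb <- B - rowMeans(B)
    sa <- sqrt(rowSums(za^2)); sb <- sqrt(rowSums(zb^2))
    sa[sa < 1e-12] <- Inf; sb[sb < 1e-12] <- Inf
    za <- za / sa; zb <- zb / sb
    best <- rep(-1, nNull)
    if (identical(attr(transforms, "dialect"), "interp45")) {
      for (tr in transforms) {
        Bt <- B %*% t(tr)
        ct <- Bt - rowMeans(Bt)
        st <- sqrt(rowSums(ct^2)); st[st < 1e-12] <- Inf
        best <- pmax(best, rowSums(za * (ct / st)))
      }
    } else {
      for (tr in transforms) best <- pmax(best, rowSums(za * zb[, tr]))
    }
    zn <- atanh(pmin(pmax(best, -1 + 1e-12), 1 - 1e-12))
    c(mean = mean(zn), sd = sd(zn))
  })
}

#' Binarize a similarity matrix by FDR thresholding
#'
#' Assigns each upper-triangle similarity r a one-sided p-value, applies
#' Benjamini-Hochberg across all node pairs at level \code{q}, and keeps
#' as edges the pairs at or below the BH cutoff. Because p is monotone in
#' r this is equivalent to a single correlation cutoff per matrix, which
#' is reported in the result; only high positive similarities become
#' edges.
#'
#' Two null models are available. The default, \code{"scramble"},
#' calibrates p against the chance level of the \emph{maximum rotated}
#' similarity: cube contents are scrambled by within-cube voxel
#' permutation (destroying spatial pattern, keeping marginals), the
#' rotation-maximized correlation is computed for \code{nNull} random
#' scrambled pairs, and a normal distribution fitted on the Fisher-z
#' scale supplies continuous p-values. This accounts for the selection
#' inflation of taking the maximum over 48 transforms (chance-level
#' maximum similarity is about 0.4, not 0) and is what makes the
#' thresholded networks sparse. It requires the \code{cubes} argument.
#'
#' \code{nullMethod = "t"} instead uses the classical correlation test:
#' \code{t = r * sqrt(df / (1 - r^2))} with
#' \code{df = nValuesPerCube - 2} (27 voxels gives df = 25), one-sided.
#' This null ignores the maximum-selection inflation, so on rotation-
#' maximized similarity matrices it retains the large majority of pairs
#' and produces near-complete graphs; it is provided for comparability
#' with plain-correlation thresholding (see the vignette).
#'
#' Alternatively a fixed correlation cutoff (for example one pooled
#' across subjects, see [pooledFDRThreshold()]) can be supplied via
#' \code{rThreshold}, and the p-value machinery is skipped.
#'
#' @param sim a \linkS4class{SimilarityMatrix}.
#' @param q FDR level in (0, 1).
#' @param nValuesPerCube values per node used in the correlation
#'   (default 27).
#' @param nullMethod \code{"scramble"} (default) or \code{"t"}; see
#'   Details.
#' @param cubes the \linkS4class{CubeSet} the matrix was built from
#'   (required for the scramble null).
#' @param nNull Monte-Carlo sample size of the scramble null.
#' @param seed seed for the scramble null.
#' @param rThreshold optional fixed correlation cutoff overriding the
#'   FDR rule (edges are pairs with r >= rThreshold).
#' @param transforms transform set (scramble null only); defaults to the
#'   48 lattice symmetries.
#' @return a \linkS4class{BinaryNetwork}.
#' @export
fdrBinarize <- function(sim, q = 0.05, nValuesPerCube = 27,
                        nullMethod = c("scramble", "t"), cubes = NULL,
                        nNull = 2000, seed = 1, rThreshold = NULL,
                        transforms = symmetryTransforms()) {
  stopifnot(is(sim, "SimilarityMatrix"))
  nullMethod <- match.arg(nullMethod)
  if (is.null(rThreshold) && (q <= 0 || q >= 1))
    stop("'q' must lie in (0, 1)")
  S <- sim@values
  n <- nrow(S)
  ut <- upper.tri(S)
  r <- S[ut]
  if (!is.null(rThreshold)) {
    keep <- r >= rThreshold
    thr <- rThreshold
  } else if (nullMethod == "t") {
    p <- corPValue(r, nValuesPerCube - 2)
    keep <- p.adjust(p, method = "BH") <= q
    thr <- if (any(keep)) min(r[keep]) else Inf
  } else {
    if (is.null(cubes))
      stop("the scramble null needs 'cubes' (the CubeSet the similarity ",
           "matrix was built from); pass it or use nullMethod = \"t\"")
    mom <- scrambleNullMoments(cubes@values, transforms, nNull, seed)
    z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    p <- pnorm(z, mean = mom["mean"], sd = mom["sd"], lower.tail = FALSE)
    keep <- p.adjust(p, method = "BH") <= q
    thr <- if (any(keep)) min(r[keep]) else Inf
  }
  A <- matrix(0, n, n)
  A[ut][keep] <- 1
  A <- A + t(A)
  new("BinaryNetwork",
      adjacency = methods::as(Matrix::Matrix(A, sparse = TRUE),
                              "generalMatrix"),
      rThreshold = as.numeric(thr),
      qValue = if (is.null(rThreshold)) q else NA_real_)
}

#' Pooled FDR correlation threshold across subjects
#'
#' Computes one common correlation cutoff by running Benjamini-Hochberg
#' over the pooled upper-triangle similarities of several subjects'
#' matrices; pass the result as \code{rThreshold} to [fdrBinarize()] to
#' binarize every subject at the same cutoff (one threshold "for all the
#' participants", as opposed to the default per-subject FDR).
#'
#' @param sims list of \linkS4class{SimilarityMatrix}.
#' @param q FDR level in (0, 1).
#' @param nValuesPerCube values per node (default 27).
#' @param nullMethod,cubesList,nNull,seed as in [fdrBinarize()];
#'   \code{cubesList} is the list of \linkS4class{CubeSet} objects
#'   matching \code{sims} (scramble null only).
#' @return the pooled correlation cutoff (Inf when nothing survives).
#' @export
pooledFDRThreshold <- function(sims, q = 0.05, nValuesPerCube = 27,
                               nullMethod = c("scramble", "t"),
                               cubesList = NULL, nNull = 2000, seed = 1) {
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  nullMethod <- match.arg(nullMethod)
  r <- unlist(lapply(sims, function(s) s@values[upper.tri(s@values)]))
  if (nullMethod == "t") {
    p <- corPValue(r, nValuesPerCube - 2)
  } else {
    if (is.null(cubesList))
      stop("the scramble null needs 'cubesList'")
    tr <- symmetryTransforms()
    mom <- vapply(seq_along(cubesList), function(i)
      scrambleNullMoments(cubesList[[i]]@values, tr, nNull,
                          childSeed(seed, i)),
      numeric(2))
    z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    p <- pnorm(z, mean = mean(mom["mean", ]),
               sd = mean(mom["sd", ]), lower.tail = FALSE)
  }
  keep <- p.adjust(p, method = "BH") <= q
  if (any(keep)) min(r[keep]) else Inf
}
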