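#' @import methods
#' @importFrom stats cor dnorm lm median pnorm prcomp pt qt p.adjust
#'   residuals rnorm runif sd var predict coef anova as.formula complete.cases
#'   quantile setNames
#' @importFrom utils combn head
NULL

#' Gray matter volume
#'
#' A 3D gray-matter intensity grid together with its voxel geometry and an
#' in-brain mask. This is the unit of per-subject input for the network and
#' brain-age stages: a segmented, spatially normalized gray matter map, as
#' produced by a VBM preprocessing pipeline (or by [simulateVolume()]).
#'
#' @slot intensities 3D \code{array} of non-negative intensities
#'   (gray-matter density units).
#' @slot voxelSize numeric(3), voxel edge length in mm per axis.
#' @slot affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @slot mask logical 3D \code{array}, same dimensions as \code{intensities},
#'   marking in-brain voxels.
#'
#' @seealso [simulateVolume()], [gaussianSmooth()], [extractCubes()]
#' @export
setClass("GrayMatterVolume",
  representation(
    intensities = "array",
    voxelSize = "numeric",
    affine = "matrix",
    mask = "array"
  ),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@intensities)) != 3L)
      msg <- c(msg, "'intensities' must be a 3D array")
    if (any(object@intensities < 0, na.rm = TRUE))
      msg <- c(msg, "'intensities' must be non-negative")
    if (!identical(dim(object@mask), dim(object@intensities)))
      msg <- c(msg, "'mask' dimensions must equal 'intensities' dimensions")
    if (!is.logical(object@mask))
      msg <- c(msg, "'mask' must be logical")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "'voxelSize' must be 3 positive values (mm)")
    if (!identical(dim(object@affine), c(4L, 4L)))
      msg <- c(msg, "'affine' must be a 4x4 matrix")
    if (length(msg)) msg else TRUE
  }
)

#' Set of cube nodes extracted from a volume
#'
#' Non-overlapping 3x3x3-voxel cubes retained as network nodes. Cubes are
#' stored row-wise: one row of 27 intensities per node, in a fixed
#' (lexicographic grid index) order so downstream outputs are reproducible.
#'
#' @slot values numeric matrix, nodes x 27, cube intensities in voxel scan
#'   order (first axis fastest).
#' @slot gridIndex integer matrix, nodes x 3, 0-based cube position on the
#'   cube grid (voxel offset is 3 * gridIndex).
#' @slot worldCenter numeric matrix, nodes x 3, mm coordinates of cube
#'   centers.
#' @slot zeroVariance logical, per node, TRUE when the 27 intensities are
#'   constant (correlation undefined; similarity is set to 0 downstream).
#'
#' @seealso [extractCubes()], [buildSimilarityMatrix()]
#' @export
setClass("CubeSet",
  representation(
    values = "matrix",
    gridIndex = "matrix",
    worldCenter = "matrix",
    zeroVariance = "logical"
  ),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@values)
    if (ncol(object@values) != 27L)
      msg <- c(msg, "'values' must have exactly 27 columns (3x3x3 voxels)")
    if (nrow(object@gridIndex) != n || ncol(object@gridIndex) != 3L)
      msg <- c(msg, "'gridIndex' must be n x 3")
    if (nrow(object@worldCenter) != n || ncol(object@worldCenter) != 3L)
      msg <- c(msg, "'worldCenter' must be n x 3")
    if (length(object@zeroVariance) != n)
      msg <- c(msg, "'zeroVariance' must have one flag per node")
    if (length(msg)) msg else TRUE
  }
)

#' Symmetry-maximized similarity matrix
#'
#' Symmetric matrix of maximum rotated correlations between cube nodes:
#' entry (i, j) is the largest Pearson correlation between the 27
#' intensities of cube i and any lattice rotation/reflection of cube j.
#' The diagonal is fixed at 1 and excluded from all downstream statistics.
#'
#' @slot values symmetric numeric matrix in [-1, 1].
#' @slot zeroVariance logical per node; flagged nodes had constant
#'   intensities and carry similarity 0 to every other node.
#'
#' @seealso [buildSimilarityMatrix()], [fdrBinarize()]
#' @export
setClass("SimilarityMatrix",
  representation(values = "matrix", zeroVariance = "logical"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (nrow(v) != ncol(v)) msg <- c(msg, "'values' must be square")
    else if (max(abs(v - t(v))) > 1e-12)
      msg <- c(msg, "'values' must be symmetric within 1e-12")
    if (any(v > 1 + 1e-12 | v < -1 - 1e-12))
      msg <- c(msg, "similarities must lie in [-1, 1]")
    if (length(object@zeroVariance) != nrow(v))
      msg <- c(msg, "'zeroVariance' must have one flag per node")
    if (length(msg)) msg else TRUE
  }
)

#' Binary (unweighted, undirected) network
#'
#' Adjacency over cube nodes after FDR thresholding of the similarity
#' matrix: no self-loops, no weights.
#'
#' @slot adjacency sparse symmetric 0/1 \code{Matrix} with zero diagonal.
#' @slot rThreshold numeric, the implied correlation cutoff: every retained
#'   similarity is >= this value (Inf for an empty graph, NA when the
#'   network was not produced by thresholding).
#' @slot qValue numeric, FDR level used (NA when not applicable).
#'
#' @seealso [fdrBinarize()], [smallWorldProperties()]
#' @export
setClass("BinaryNetwork",
  representation(adjacency = "Matrix", rThreshold = "numeric",
                 qValue = "numeric"),
  validity = function(object) {
    msg <- character()
    a <- object@adjacency
    if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
    if (any(Matrix::diag(a) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (!Matrix::isSymmetric(a)) msg <- c(msg, "adjacency must be symmetric")
    if (length(msg)) msg else TRUE
  }
)

#' Small-world network properties
#'
#' Global graph measures of one binarized gray matter network together with
#' their means over degree-preserving randomized reference graphs, and the
#' normalized (small-world) quantities derived from them: normalized
#' clustering gamma = C / C_rand, normalized path length
#' lambda = L / L_rand, and small-world coefficient sigma = gamma / lambda.
#' A network is called small-world when gamma > 1, lambda is close to 1,
#' and sigma > 1.
#'
#' @slot clusteringC mean clustering coefficient of the network.
#' @slot pathLengthL characteristic path length (mean shortest path over
#'   pairs in the largest connected component).
#' @slot CRand,LRand means of the same measures over the randomized
#'   reference graphs.
#' @slot gamma,lambda,sigma normalized clustering, normalized path length,
#'   small-world coefficient.
#' @slot nRandom number of randomized references used.
#' @slot componentFraction fraction of nodes in the largest connected
#'   component.
#'
#' @seealso [smallWorldProperties()]
#' @export
setClass("NetworkProperties",
  representation(
    clusteringC = "numeric", pathLengthL = "numeric",
    CRand = "numeric", LRand = "numeric",
    gamma = "numeric", lambda = "numeric", sigma = "numeric",
    nRandom = "integer", componentFraction = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@nRandom < 1L) msg <- c(msg, "'nRandom' must be >= 1")
    if (is.finite(object@sigma) && is.finite(object@gamma) &&
        is.finite(object@lambda) &&
        abs(object@sigma - object@gamma / object@lambda) >
          1e-12 * max(1, abs(object@sigma)))
      msg <- c(msg, "'sigma' must equal gamma / lambda")
    if (length(msg)) msg else TRUE
  }
)

#' Cross-validated brain-age prediction result
#'
#' Held-out predictions from K-fold cross-validated principal-component
#' support-vector regression of chronological age on voxel intensities,
#' with pooled accuracy measures and the per-subject brain-predicted age
#' difference (brain-PAD = predicted age - chronological age).
#'
#' @slot predicted held-out predicted age (years), one per subject.
#' @slot ages chronological age (years).
#' @slot brainPAD predicted - chronological, per subject.
#' @slot foldId integer fold assignment per subject.
#' @slot mae mean absolute error (years), pooled over held-out folds.
#' @slot rmse root-mean-square error (years).
#' @slot r Pearson correlation between predicted and chronological age
#'   (NA when chronological age is constant).
#' @slot nComponents number of principal components actually used (may be
#'   lower than requested when the training fold rank is smaller).
#' @slot folds number of cross-validation folds.
#' @slot seed seed used for fold assignment.
#'
#' @seealso [fitBrainAgeCV()], [brainPAD()]
#' @export
setClass("BrainAgeResult",
  representation(
    predicted = "numeric", ages = "numeric", brainPAD = "numeric",
    foldId = "integer", mae = "numeric", rmse = "numeric", r = "numeric",
    nComponents = "integer", folds = "integer", seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    n <- length(object@ages)
    if (length(object@predicted) != n || length(object@brainPAD) != n ||
        length(object@foldId) != n)
      msg <- c(msg, "per-subject slots must have equal length")
    if (n > 0 && max(abs(object@brainPAD - (object@predicted - object@ages))) >
        1e-8)
      msg <- c(msg, "'brainPAD' must equal predicted - ages")
    if (length(object@mae) && length(object@rmse) &&
        is.finite(object@mae) && is.finite(object@rmse) &&
        object@mae > object@rmse + 1e-10)
      msg <- c(msg, "MAE cannot exceed RMSE")
    if (length(msg)) msg else TRUE
  }
)
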