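#' Number of nodes
#'
#' @param x a \linkS4class{CubeSet}, \linkS4class{SimilarityMatrix} or
#'   \linkS4class{BinaryNetwork}.
#' @return integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "CubeSet", function(x) nrow(x@values))

#' @rdname nNodes
#' @export
setMethod("nNodes", "SimilarityMatrix", function(x) nrow(x@values))

#' @rdname nNodes
#' @export
setMethod("nNodes", "BinaryNetwork", function(x) nrow(x@adjacency))

#' Number of edges of a binary network
#'
#' @param x a \linkS4class{BinaryNetwork}.
#' @return integer edge count (half the sum of the adjacency matrix).
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname nEdges
#' @export
setMethod("nEdges", "BinaryNetwork",
          function(x) as.integer(Matrix::nnzero(x@adjacency) / 2))

#' Accessors for volumes, cubes, similarity matrices and networks
#'
#' \code{intensities}, \code{voxelSize} and \code{brainMask} read the slots
#' of a \linkS4class{GrayMatterVolume}; \code{cubeValues} and
#' \code{gridIndex} read a \linkS4class{CubeSet}; \code{simValues} returns
#' the dense similarity matrix; \code{adjacency} the sparse 0/1 adjacency;
#' \code{rThreshold} the implied correlation cutoff of the FDR
#' binarization.
#'
#' @param x the object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "GrayMatterVolume", function(x) x@intensities)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "GrayMatterVolume", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setMethod("brainMask", "GrayMatterVolume", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))
#' @rdname accessors
#' @export
setMethod("cubeValues", "CubeSet", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("gridIndex", function(x) standardGeneric("gridIndex"))
#' @rdname accessors
#' @export
setMethod("gridIndex", "CubeSet", function(x) x@gridIndex)

#' @rdname accessors
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))
#' @rdname accessors
#' @export
setMethod("simValues", "SimilarityMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setMethod("adjacency", "BinaryNetwork", function(x) x@adjacency)

#' @rdname accessors
#' @export
setGeneric("rThreshold", function(x) standardGeneric("rThreshold"))
#' @rdname accessors
#' @export
setMethod("rThreshold", "BinaryNetwork", function(x) x@rThreshold)

#' Small-world property accessors
#'
#' @param x a \linkS4class{NetworkProperties} object.
#' @return numeric scalar.
#' @name smallWorldAccessors
NULL

#' @rdname smallWorldAccessors
#' @export
setGeneric("normClustering", function(x) standardGeneric("normClustering"))
#' @rdname smallWorldAccessors
#' @export
setMethod("normClustering", "NetworkProperties", function(x) x@gamma)

#' @rdname smallWorldAccessors
#' @export
setGeneric("normPathLength", function(x) standardGeneric("normPathLength"))
#' @rdname smallWorldAccessors
#' @export
setMethod("normPathLength", "NetworkProperties", function(x) x@lambda)

#' @rdname smallWorldAccessors
#' @export
setGeneric("smallWorldCoef", function(x) standardGeneric("smallWorldCoef"))
#' @rdname smallWorldAccessors
#' @export
setMethod("smallWorldCoef", "NetworkProperties", function(x) x@sigma)

#' @describeIn NetworkProperties-class one-row data.frame of all measures.
#' @param x a \code{NetworkProperties} object.
#' @param row.names,optional,... passed through (unused).
#' @export
setMethod("as.data.frame", "NetworkProperties",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(C = x@clusteringC, L = x@pathLengthL,
               C_rand = x@CRand, L_rand = x@LRand,
               gamma = x@gamma, lambda = x@lambda, sigma = x@sigma,
               n_random = x@nRandom,
               component_fraction = x@componentFraction)
  })

#' @describeIn BrainAgeResult-class per-subject data.frame
#'   (age, predicted_age, brain_pad, fold).
#' @param x a \code{BrainAgeResult} object.
#' @param row.names,optional,... passed through (unused).
#' @export
setMethod("as.data.frame", "BrainAgeResult",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(age = x@ages, predicted_age = x@predicted,
               brain_pad = x@brainPAD, fold = x@foldId)
  })

setMethod("show", "GrayMatterVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf(
    "GrayMatterVolume: %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d in mask\n",
    d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
    object@voxelSize[3], sum(object@mask)))
})

setMethod("show", "CubeSet", function(object) {
  cat(sprintf("CubeSet: %d nodes of 3x3x3 voxels (%d zero-variance)\n",
              nrow(object@values), sum(object@zeroVariance)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat(sprintf(
    "SimilarityMatrix: %d nodes; off-diagonal range [%.3f, %.3f], median %.3f\n",
    nrow(object@values), min(v), max(v), median(v)))
})

setMethod("show", "BinaryNetwork", function(object) {
  n <- nrow(object@adjacency)
  e <- nEdges(object)
  dens <- if (n > 1) e / (n * (n - 1) / 2) else NA_real_
  cat(sprintf("BinaryNetwork: %d nodes, %d edges (density %.4f)", n, e, dens))
  if (length(object@rThreshold) && is.finite(object@rThreshold))
    cat(sprintf(", r threshold %.4f (q = %.3g)", object@rThreshold,
                object@qValue))
  cat("\n")
})

setMethod("show", "NetworkProperties", function(object) {
  cat("NetworkProperties:\n")
  cat(sprintf("  C = %.4f  (C_rand = %.4f over %d references)\n",
              object@clusteringC, object@CRand, object@nRandom))
  cat(sprintf("  L = %.4f  (L_rand = %.4f)\n", object@pathLengthL,
              object@LRand))
  cat(sprintf("  gamma = %.4f  lambda = %.4f  sigma = %.4f\n",
              object@gamma, object@lambda, object@sigma))
  sw <- object@gamma > 1 && object@sigma > 1
  cat(sprintf("  small-world (gamma > 1 and sigma > 1): %s\n",
              if (sw) "yes" else "no"))
})

setMethod("show", "BrainAgeResult", function(object) {
  cat(sprintf(
    "BrainAgeResult: %d subjects, %d-fold CV, %d components\n",
    length(object@ages), object@folds, object@nComponents))
  cat(sprintf("  MAE = %.3f y  RMSE = %.3f y  r = %.3f  mean brain-PAD = %.3f y\n",
              object@mae, object@rmse, object@r, mean(object@brainPAD)))
})
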