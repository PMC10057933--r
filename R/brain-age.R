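# Brain-age prediction: PCA of voxel intensities + linear support-vector
# regression, K-fold cross-validated, and the brain-PAD score.

#' Stack volumes into a subjects-by-voxels feature table
#'
#' Extracts the in-mask voxel intensities of each volume as one row, in a
#' fixed voxel (array scan) order. All volumes must share grid dimensions;
#' by default the mask is the intersection of the per-volume brain masks.
#' Columns that are constant across subjects are flagged in the
#' \code{"constantColumns"} attribute.
#'
#' @param volumes list of \linkS4class{GrayMatterVolume} on one grid.
#' @param mask optional logical 3D array selecting the voxels to use.
#' @return numeric matrix (subjects x voxels) with attributes
#'   \code{"maskIndices"} (linear voxel indices) and
#'   \code{"constantColumns"}.
#' @export
vectorizeVolumes <- function(volumes, mask = NULL) {
  stopifnot(length(volumes) >= 1)
  d <- dim(volumes[[1]]@intensities)
  for (v in volumes)
    if (!identical(dim(v@intensities), d))
      stop("all volumes must share the same grid dimensions")
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(volumes, function(v) v@mask))
  } else if (!identical(dim(mask), d)) {
    stop("mask dimensions must match the volume grid")
  }
  idx <- which(mask)
  X <- t(vapply(volumes, function(v) v@intensities[idx],
                numeric(length(idx))))
  cc <- apply(X, 2, function(col) max(col) - min(col) < 1e-12)
  if (any(cc))
    warning(sprintf("%d voxel column(s) are constant across subjects",
                    sum(cc)))
  structure(X, maskIndices = idx, constantColumns = which(cc))
}

#' Brain-age model settings
#'
#' Bundles the settings of the principal-component support-vector
#' regression: number of components (100 at full scale; tests use fewer,
#' capped at the training-fold rank), the SVR variant (nu-SVR with a
#' linear kernel, C = 1, nu = 0.5 — the LIBSVM defaults — or epsilon-SVR
#' as a fallback reading of the same flags), and the number of
#' cross-validation folds.
#'
#' @param nComponents principal components retained (default 100).
#' @param folds cross-validation folds (default 10, >= 2).
#' @param svrType \code{"nu"} (default) or \code{"eps"}.
#' @param cost SVR cost parameter C (default 1).
#' @param nu nu parameter of nu-SVR (default 0.5).
#' @param epsilon epsilon of eps-SVR (used only when
#'   \code{svrType = "eps"}).
#' @param globalBasis fit the PCA basis on all subjects instead of per
#'   training fold (leaks test data into the basis; off by default,
#'   available for replicating pipelines that are ambiguous about it).
#' @param standardize z-score voxel columns before PCA (off by default;
#'   gray matter intensities are commensurate across voxels).
#' @return a list of class \code{BrainAgeModel}.
#' @export
brainAgeModel <- function(nComponents = 100, folds = 10,
                          svrType = c("nu", "eps"), cost = 1, nu = 0.5,
                          epsilon = 0.1, globalBasis = FALSE,
                          standardize = FALSE) {
  svrType <- match.arg(svrType)
  if (folds < 2) stop("'folds' must be >= 2")
  if (nComponents < 1) stop("'nComponents' must be >= 1")
  structure(list(nComponents = as.integer(nComponents),
                 folds = as.integer(folds), svrType = svrType, cost = cost,
                 nu = nu, epsilon = epsilon, globalBasis = globalBasis,
                 standardize = standardize),
            class = "BrainAgeModel")
}

# deterministic, order-invariant fold assignment: subjects ranked by id
# hash and dealt round-robin; without ids, a seeded random permutation
assignFolds <- function(n, folds, seed, ids = NULL) {
  if (!is.null(ids)) {
    stopifnot(length(ids) == n, !anyDuplicated(ids))
    ord <- order(stringHash(paste0(ids, "#", seed)), ids)
    f <- integer(n)
    f[ord] <- rep_len(seq_len(folds), n)
    f
  } else {
    withSeed(seed, sample(rep_len(seq_len(folds), n)))
  }
}

#' Cross-validated brain-age prediction
#'
#' Predicts chronological age from voxel features by principal-component
#' reduction followed by support-vector regression with a linear kernel,
#' under K-fold cross-validation: for each fold, the PCA basis and the
#' SVR are fitted on the training folds only and ages of the held-out
#' fold are predicted with them, so no test information leaks into the
#' model. Pooled held-out predictions give the mean absolute error,
#' root-mean-square error and the correlation r between predicted and
#' chronological age, plus the per-subject brain-PAD
#' (predicted - chronological).
#'
#' The number of components is capped at the training-fold rank (with a
#' warning) when the requested value is not attainable. When \code{ids}
#' are supplied, fold assignment is a deterministic function of the id
#' hashes, so results do not depend on subject order.
#'
#' @param features subjects x voxels matrix (see [vectorizeVolumes()]).
#' @param ages chronological ages, years.
#' @param model a [brainAgeModel()].
#' @param seed seed for fold assignment.
#' @param ids optional unique subject ids for order-invariant fold
#'   assignment.
#' @return a \linkS4class{BrainAgeResult}.
#' @examples
#' X <- matrix(rnorm(60 * 30), 60)
#' ages <- 40 + 10 * X[, 1] + rnorm(60)
#' fitBrainAgeCV(X, ages, brainAgeModel(nComponents = 5, folds = 5),
#'               seed = 1)
#' @export
fitBrainAgeCV <- function(features, ages, model = brainAgeModel(),
                          seed = 1, ids = NULL) {
  stopifnot(inherits(model, "BrainAgeModel"))
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(ages) != n) stop("'ages' must match the number of rows")
  if (!all(is.finite(ages))) stop("'ages' must be finite")
  if (n < model$folds) stop("need at least as many subjects as folds")
  foldId <- assignFolds(n, model$folds, seed, ids)
  predicted <- numeric(n)
  usedComp <- model$nComponents
  globalPCA <- NULL
  if (model$globalBasis)
    globalPCA <- prcomp(features, center = TRUE,
                        scale. = model$standardize,
                        rank. = model$nComponents)
  for (f in seq_len(model$folds)) {
    test <- foldId == f
    Xtr <- features[!test, , drop = FALSE]
    if (is.null(globalPCA)) {
      maxRank <- min(nrow(Xtr) - 1L, ncol(Xtr))
      k <- min(model$nComponents, maxRank)
      pca <- prcomp(Xtr, center = TRUE, scale. = model$standardize,
                    rank. = k)
      k <- ncol(pca$rotation)        # prcomp may return fewer columns
    } else {
      pca <- globalPCA
      k <- ncol(pca$rotation)
    }
    usedComp <- min(usedComp, k)
    project <- function(X) {
      Xc <- sweep(X, 2, pca$center)
      if (!identical(pca$scale, FALSE)) Xc <- sweep(Xc, 2, pca$scale, "/")
      Xc %*% pca$rotation[, seq_len(k), drop = FALSE]
    }
    Ztr <- project(Xtr)
    Zte <- project(features[test, , drop = FALSE])
    if (sd(ages[!test]) < 1e-12) {      # degenerate target: no regression
      predicted[test] <- mean(ages[!test])
      next
    }
    fit <- e1071::svm(
      x = Ztr, y = ages[!test],
      type = if (model$svrType == "nu") "nu-regression" else "eps-regression",
      kernel = "linear", cost = model$cost, nu = model$nu,
      epsilon = model$epsilon, scale = FALSE)
    predicted[test] <- as.numeric(predict(fit, Zte))
  }
  if (usedComp < model$nComponents)
    warning(sprintf(
      "number of components reduced from %d to %d (training-fold rank)",
      model$nComponents, usedComp))
  err <- predicted - ages
  r <- if (sd(ages) < 1e-12) {
    warning("chronological age is constant; correlation undefined")
    NA_real_
  } else cor(predicted, ages)
  new("BrainAgeResult",
      predicted = predicted, ages = as.numeric(ages),
      brainPAD = err, foldId = as.integer(foldId),
      mae = mean(abs(err)), rmse = sqrt(mean(err^2)), r = r,
      nComponents = as.integer(usedComp), folds = model$folds,
      seed = as.integer(seed))
}

#' Brain-predicted age difference (brain-PAD)
#'
#' The brain-PAD score of a subject is the predicted brain age minus the
#' chronological age, in years; positive values indicate an
#' "older-looking" brain.
#'
#' @param predicted predicted age(s), years.
#' @param chronological chronological age(s), years.
#' @return predicted - chronological, vectorized.
#' @examples
#' brainPAD(58, 60)
#' @export
brainPAD <- function(predicted, chronological) {
  if (!all(is.finite(predicted)) || !all(is.finite(chronological)))
    stop("ages must be finite")
  predicted - chronological
}
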