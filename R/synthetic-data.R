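# Synthetic gray matter volumes and cohorts.
#
# Downstream stages consume only the smoothed, normalized gray matter map,
# so segmentation/registration is not emulated: volumes are synthesized
# directly as spatially structured random fields inside an ellipsoidal
# brain mask.

# ---- Gaussian smoothing ------------------------------------------------

# 1D discrete Gaussian kernel, unit sum; sigma in voxels
gaussKernel1D <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# n x n smoothing operator with mass-conserving (column-renormalized)
# boundary handling: each input voxel redistributes weight summing to 1.
smoothOperator1D <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - r):(j + r)
    ok <- idx >= 1L & idx <= n
    w <- kernel[ok]
    M[idx[ok], j] <- w / sum(w)
  }
  M
}

# apply a 1D operator along one axis of a 3D array
applyAlongAxis <- function(a, axis, M) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  m <- M %*% m
  ap <- array(m, dim = dp)
  aperm(ap, order(perm))
}

smoothArray <- function(a, sigmaVox) {
  for (axis in 1:3) {
    if (sigmaVox[axis] > 0) {
      k <- gaussKernel1D(sigmaVox[axis])
      if (length(k) > 1L)
        a <- applyAlongAxis(a, axis, smoothOperator1D(dim(a)[axis], k))
    }
  }
  a
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable discrete Gaussian convolution at a given full width at half
#' maximum (FWHM); per axis the kernel standard deviation is
#' \code{(fwhm / 2.3548) / voxelSize} voxels. Boundary handling is
#' mass-conserving ("conservative"): the kernel is renormalized at the
#' edges so that every input voxel redistributes a total weight of exactly
#' one, and the total intensity of the volume is conserved. The operation
#' is linear in the input.
#'
#' @param x a \linkS4class{GrayMatterVolume} or a 3D numeric array.
#' @param fwhm full width at half maximum of the kernel, mm (>= 0; 0
#'   returns the input unchanged).
#' @param voxelSize voxel size in mm (scalar or length 3); taken from the
#'   volume when \code{x} is a \code{GrayMatterVolume}.
#' @return an object of the same kind as \code{x} with smoothed
#'   intensities.
#' @examples
#' v <- simulateVolume(shape = c(12, 12, 12), seed = 1)
#' sm <- gaussianSmooth(v, fwhm = 8)
#' all.equal(sum(intensities(sm)), sum(intensities(v)))
#' @export
setGeneric("gaussianSmooth",
           function(x, fwhm, voxelSize = 1) standardGeneric("gaussianSmooth"))

#' @rdname gaussianSmooth
#' @export
setMethod("gaussianSmooth", "array", function(x, fwhm, voxelSize = 1) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm < 0)
    stop("'fwhm' must be a single non-negative number (mm)")
  if (fwhm == 0) return(x)
  vs <- rep_len(voxelSize, 3L)
  smoothArray(x, (fwhm / (2 * sqrt(2 * log(2)))) / vs)
})

#' @rdname gaussianSmooth
#' @export
setMethod("gaussianSmooth", "GrayMatterVolume", function(x, fwhm,
                                                         voxelSize = 1) {
  out <- callGeneric(x@intensities, fwhm, x@voxelSize)
  new("GrayMatterVolume", intensities = out, voxelSize = x@voxelSize,
      affine = x@affine, mask = x@mask)
})

# ---- Volume synthesis --------------------------------------------------

ellipsoidMask <- function(shape) {
  ctr <- (shape + 1) / 2
  rad <- shape / 2
  ax <- (seq_len(shape[1]) - ctr[1]) / rad[1]
  ay <- (seq_len(shape[2]) - ctr[2]) / rad[2]
  az <- (seq_len(shape[3]) - ctr[3]) / rad[3]
  outer(outer(ax^2, ay^2, `+`), az^2, `+`) <= 1
}

defaultAffine <- function(voxelSize) {
  a <- diag(c(voxelSize, 1))
  a
}

# smooth a field defined over the cube grid (sigma in cube units)
smoothCubeField <- function(arr, sigma) {
  k <- gaussKernel1D(sigma)
  if (length(k) == 1L) return(arr)
  for (axis in 1:3)
    arr <- applyAlongAxis(arr, axis, smoothOperator1D(dim(arr)[axis], k))
  arr
}

#' Simulate one gray-matter-like volume
#'
#' Generates a non-negative random field standing in for a segmented,
#' spatially normalized gray matter map, with the covariance structure
#' that similarity-based network analysis assumes: nearby 3x3x3-voxel
#' cubes share fine-scale tissue pattern, distant cubes mostly do not.
#'
#' The construction is a latent tissue-motif model of structural
#' covariance. \code{nMotifs} independent white 27-vector motifs (local
#' tissue patterns) are mixed with spatially smooth, sharply peaked
#' weights defined over the cube grid (Gaussian random fields with
#' standard deviation \code{motifScale} cubes, passed through
#' \code{exp(motifSharpness * z)} and normalized), so each brain
#' neighbourhood is dominated by a few motifs that vary smoothly across
#' space. Each cube's pattern is
#' \code{s * motifMixture + sqrt(1 - s^2) * noise} with
#' \code{s = covarianceStrength}: \code{s} is the fraction of pattern
#' correlation shared between cubes dominated by the same motifs, and 0
#' yields pure i.i.d. voxel noise. The assembled volume is optionally
#' smoothed at \code{fwhm}, mapped to gray-matter-density-like units
#' (\code{0.55 + 0.15 * X}), clipped at zero and zeroed outside an
#' ellipsoidal brain mask inscribed in the grid. Deterministic given
#' \code{seed}.
#'
#' Because motifs are white at the voxel scale, unrelated cube pairs
#' behave like the chance (scrambled-cube) null of the maximum rotated
#' similarity, while related pairs rise above it — which is what makes
#' the FDR-thresholded networks sparse and small-world, as observed for
#' real gray matter (see the package vignette for the design rationale).
#'
#' @param shape integer(3) grid dimensions; each must be >= 9 voxels so
#'   that a meaningful 3x3x3 cube grid exists.
#' @param voxelSize voxel edge length, mm (scalar or length 3; default
#'   6 mm so that the standard 8 mm FWHM network smoothing is mild at the
#'   cube scale).
#' @param fwhm smoothing applied to the assembled field, mm (default 0:
#'   the caller applies the stage-appropriate smoothing, 8 mm for
#'   networks, 4 mm for brain age).
#' @param covarianceStrength in [0, 1]; 0 gives i.i.d. voxel noise,
#'   values near 1 a strongly covarying field.
#' @param seed integer seed.
#' @param nMotifs number of latent tissue motifs (default 40).
#' @param motifScale smoothness of the motif weight fields, in cube
#'   units (default 1.2).
#' @param motifSharpness exponent applied to the standardized weight
#'   fields (default 3; larger values make motif territories more
#'   block-like).
#' @return a \linkS4class{GrayMatterVolume}.
#' @examples
#' v <- simulateVolume(shape = c(15, 15, 15), covarianceStrength = 0.8,
#'                     seed = 7)
#' v
#' @export
simulateVolume <- function(shape = c(30, 30, 30), voxelSize = 6, fwhm = 0,
                           covarianceStrength = 0.8, seed = 1,
                           nMotifs = 40, motifScale = 1.2,
                           motifSharpness = 3) {
  shape <- as.integer(rep_len(shape, 3L))
  if (any(shape < 9L))
    stop("each volume dimension must be >= 9 voxels for a usable cube grid")
  if (covarianceStrength < 0 || covarianceStrength > 1)
    stop("'covarianceStrength' must lie in [0, 1]")
  vs <- rep_len(as.numeric(voxelSize), 3L)
  s <- covarianceStrength
  nc <- shape %/% 3L
  x <- withSeed(seed, {
    if (s > 0) {
      M <- matrix(rnorm(27 * nMotifs), nMotifs, 27)
      W <- vapply(seq_len(nMotifs), function(k)
        as.numeric(smoothCubeField(array(rnorm(prod(nc)), nc), motifScale)),
        numeric(prod(nc)))
      W <- exp(motifSharpness * scale(W))
      W <- W / sqrt(rowSums(W^2))
      P <- W %*% M
      P <- P / apply(P, 1, sd)
      X <- s * P + sqrt(1 - s^2) * matrix(rnorm(nrow(P) * 27), nrow(P), 27)
    } else {
      X <- matrix(rnorm(prod(nc) * 27), prod(nc), 27)
    }
    a <- array(rnorm(prod(shape)), shape)  # voxels outside the cube tiling
    cubeGrid <- as.matrix(expand.grid(0:(nc[1] - 1L), 0:(nc[2] - 1L),
                                      0:(nc[3] - 1L)))
    for (i in seq_len(nrow(cubeGrid)))
      a[3L * cubeGrid[i, 1] + 1:3, 3L * cubeGrid[i, 2] + 1:3,
        3L * cubeGrid[i, 3] + 1:3] <- array(X[i, ], c(3, 3, 3))
    a
  })
  if (fwhm > 0) x <- gaussianSmooth(x, fwhm, vs)
  mask <- ellipsoidMask(shape)
  gm <- pmax(0.55 + 0.15 * x, 0)
  gm[!mask] <- 0
  new("GrayMatterVolume", intensities = gm, voxelSize = vs,
      affine = defaultAffine(vs), mask = mask)
}

# ---- Cohort specification and generation -------------------------------

#' Cohort specification
#'
#' Bundles the sampling design of a synthetic cohort: size, age range,
#' sex balance, scanner labels, and the linear-with-changepoint model that
#' ties each subject's spatial covariance strength to age and sex:
#' \deqn{s_i = baseline - ageSlope \cdot age_i + sexOffset \cdot F_i -
#'       extraFemaleSlope \cdot \max(0, age_i - changepoint) \cdot F_i +
#'       \epsilon_i}
#' with \eqn{F_i = 1} for women and \eqn{\epsilon_i \sim N(0, noiseSD^2)}.
#' The changepoint encodes a steeper female decline late in life.
#'
#' Defaults emulate the cohort the pipeline targets: 812 subjects, ages
#' 25.8-85.1 uniformly, 407 women / 405 men, two scanners, changepoint at
#' 70 years.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param ageRange numeric(2), min < max, years.
#' @param sexRatio fraction of women in [0, 1]; counts are exact
#'   (\code{round(nSubjects * sexRatio)} women).
#' @param scannerLabels two scanner labels, assigned alternately.
#' @param baseline,ageSlope,sexOffset,changepoint,extraFemaleSlope,noiseSD
#'   effect parameters of the covariance-strength model (changepoint
#'   \code{NA} disables the late-life term).
#' @param shape,voxelSize,nMotifs,motifScale,motifSharpness geometry and
#'   motif-model settings passed to [simulateVolume()].
#' @param seed master seed; all randomness in [simulateCohort()] derives
#'   from it.
#' @return a list of class \code{CohortSpec}.
#' @examples
#' spec <- cohortSpec(nSubjects = 10, seed = 3)
#' coh <- simulateCohort(spec, makeVolumes = FALSE)
#' table(coh$table$sex)
#' @export
cohortSpec <- function(nSubjects = 812, ageRange = c(25.8, 85.1),
                       sexRatio = 407 / 812,
                       scannerLabels = c("scannerA", "scannerB"),
                       baseline = 0.95, ageSlope = 0.004, sexOffset = 0.02,
                       changepoint = 70, extraFemaleSlope = 0.008,
                       noiseSD = 0.02, shape = c(30, 30, 30), voxelSize = 6,
                       nMotifs = 40, motifScale = 1.2, motifSharpness = 3,
                       seed = 1) {
  if (nSubjects < 1) stop("'nSubjects' must be >= 1")
  if (sexRatio < 0 || sexRatio > 1) stop("'sexRatio' must lie in [0, 1]")
  if (ageRange[1] >= ageRange[2]) stop("'ageRange' must satisfy min < max")
  if (length(scannerLabels) != 2L) stop("exactly two scanner labels expected")
  if (!is.na(changepoint) &&
      (changepoint < ageRange[1] || changepoint > ageRange[2]))
    stop("'changepoint' must lie within 'ageRange' (or be NA to disable)")
  structure(list(
    nSubjects = as.integer(nSubjects), ageRange = ageRange,
    sexRatio = sexRatio, scannerLabels = scannerLabels,
    baseline = baseline, ageSlope = ageSlope, sexOffset = sexOffset,
    changepoint = changepoint, extraFemaleSlope = extraFemaleSlope,
    noiseSD = noiseSD, shape = shape, voxelSize = voxelSize,
    nMotifs = nMotifs, motifScale = motifScale,
    motifSharpness = motifSharpness, seed = as.integer(seed)
  ), class = "CohortSpec")
}

covarianceStrengthModel <- function(spec, age, female) {
  cp <- spec$changepoint
  post <- if (is.na(cp)) 0 else pmax(0, age - cp)
  spec$baseline - spec$ageSlope * age + spec$sexOffset * female -
    spec$extraFemaleSlope * post * female
}

#' Simulate a cohort of subjects and volumes
#'
#' Draws ages uniformly over the spec's range, assigns sexes with exact
#' counts and scanners alternately, computes each subject's spatial
#' covariance strength from the linear-with-changepoint model in
#' [cohortSpec()] (plus Gaussian noise, clipped into [0, 1] with a warning
#' when clipping occurs), and synthesizes one unsmoothed volume per
#' subject via [simulateVolume()]. Everything is deterministic given the
#' spec's seed.
#'
#' @param spec a [cohortSpec()].
#' @param makeVolumes generate the per-subject volumes (set \code{FALSE}
#'   for table-only cohorts, e.g. when testing the statistical stage).
#' @return list with \code{table} (data.frame: id, age, sex, scanner,
#'   covariance_strength) and \code{volumes} (named list of
#'   \linkS4class{GrayMatterVolume}, or NULL).
#' @export
simulateCohort <- function(spec, makeVolumes = TRUE) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$nSubjects
  nF <- round(spec$sexRatio * n)
  tab <- withSeed(spec$seed, {
    age <- runif(n, spec$ageRange[1], spec$ageRange[2])
    sex <- sample(rep(c("F", "M"), c(nF, n - nF)))
    noise <- rnorm(n, sd = spec$noiseSD)
    data.frame(
      id = sprintf("sub%04d", seq_len(n)),
      age = age, sex = sex,
      scanner = spec$scannerLabels[(seq_len(n) - 1L) %% 2L + 1L],
      stringsAsFactors = FALSE
    ) -> d
    d$covariance_strength <-
      covarianceStrengthModel(spec, d$age, as.numeric(d$sex == "F")) + noise
    d
  })
  if (any(tab$covariance_strength < 0 | tab$covariance_strength > 1)) {
    warning("covariance strength clipped into [0, 1] for some subjects")
    tab$covariance_strength <- pmin(pmax(tab$covariance_strength, 0), 1)
  }
  vols <- NULL
  if (makeVolumes) {
    vols <- lapply(seq_len(n), function(i)
      simulateVolume(shape = spec$shape, voxelSize = spec$voxelSize,
                     fwhm = 0, covarianceStrength = tab$covariance_strength[i],
                     seed = childSeed(spec$seed, i), nMotifs = spec$nMotifs,
                     motifScale = spec$motifScale,
                     motifSharpness = spec$motifSharpness))
    names(vols) <- tab$id
  }
  list(table = tab, volumes = vols)
}

#' Simulate a per-subject network-property table
#'
#' Generates the subject-level table the statistical stage consumes
#' (id, age, sex, scanner, n_nodes, gamma, lambda, sigma, predicted_age,
#' brain_pad) directly from a linear-with-changepoint effect model,
#' without synthesizing volumes. Used to study the statistical stage at
#' cohort scale: normalized clustering and normalized path length each
#' follow \code{base + ageSlope * (age - 25) + sexOffset * F +
#' interactionSlope * max(0, age - changepoint) * F + noise}, the
#' small-world coefficient is gamma / lambda by definition, node counts
#' are sex-dependent Gaussians, and predicted age is chronological age
#' plus Gaussian error.
#'
#' Default magnitudes are anchored to the scale on which these measures
#' live in single-subject gray matter network studies (gamma around
#' 1.65-1.76, lambda around 1.10, node counts near 6400/7100 for
#' women/men, brain-PAD standard deviation near 5 years).
#'
#' @param n subjects.
#' @param seed integer seed.
#' @param ageRange years, ages drawn uniformly.
#' @param sexRatio fraction of women (exact counts).
#' @param gammaBase,gammaAgeSlope,gammaSexOffset gamma model: intercept at
#'   age 25, decline per year, additive female offset.
#' @param lambdaBase,lambdaAgeSlope,lambdaSexOffset same for lambda.
#' @param changepoint years; NA disables the late-life interaction.
#' @param gammaInteraction,lambdaInteraction extra female slope per year
#'   beyond the changepoint (negative = steeper female decline).
#' @param gammaSD,lambdaSD residual standard deviations.
#' @param nodesMeanF,nodesMeanM,nodesSD node-count model.
#' @param brainAgeSD standard deviation (years) of predicted - true age.
#' @return data.frame with one row per subject.
#' @examples
#' tab <- simulatePropertyTable(n = 100, seed = 1)
#' head(tab)
#' @export
simulatePropertyTable <- function(n, seed = 1, ageRange = c(25.8, 85.1),
                                  sexRatio = 0.5,
                                  gammaBase = 1.85, gammaAgeSlope = -0.0035,
                                  gammaSexOffset = 0.026,
                                  lambdaBase = 1.13, lambdaAgeSlope = -6e-4,
                                  lambdaSexOffset = 0.005,
                                  changepoint = 70,
                                  gammaInteraction = -0.0035,
                                  lambdaInteraction = -0.0007,
                                  gammaSD = 0.05, lambdaSD = 0.012,
                                  nodesMeanF = 6378, nodesMeanM = 7092,
                                  nodesSD = 486, brainAgeSD = 5) {
  stopifnot(n >= 1)
  nF <- round(sexRatio * n)
  withSeed(seed, {
    age <- runif(n, ageRange[1], ageRange[2])
    sex <- sample(rep(c("F", "M"), c(nF, n - nF)))
    f <- as.numeric(sex == "F")
    post <- if (is.na(changepoint)) 0 else pmax(0, age - changepoint)
    gamma <- gammaBase + gammaAgeSlope * (age - 25) + gammaSexOffset * f +
      gammaInteraction * post * f + rnorm(n, sd = gammaSD)
    lambda <- lambdaBase + lambdaAgeSlope * (age - 25) + lambdaSexOffset * f +
      lambdaInteraction * post * f + rnorm(n, sd = lambdaSD)
    nn <- round(rnorm(n, mean = ifelse(sex == "F", nodesMeanF, nodesMeanM),
                      sd = nodesSD))
    pred <- age + rnorm(n, sd = brainAgeSD)
    data.frame(
      id = sprintf("sub%04d", seq_len(n)), age = age, sex = sex,
      scanner = c("scannerA", "scannerB")[(seq_len(n) - 1L) %% 2L + 1L],
      n_nodes = nn, gamma = gamma, lambda = lambda, sigma = gamma / lambda,
      predicted_age = pred, brain_pad = pred - age,
      stringsAsFactors = FALSE
    )
  })
}
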