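# Pipeline configuration and stage runners tying the modules into one
# reproducible analysis: simulate -> network -> brainage -> analyze.
# All file formats are text or standard neuroimaging formats: NIfTI-1
# volumes, CSV tables, Matrix Market adjacency, JSON config/manifests.

#' Pipeline configuration
#'
#' Builds and validates the configuration for a full pipeline run. One
#' master seed is fanned out deterministically to every stochastic stage
#' (cohort sampling, per-subject volumes, null calibration, network
#' randomization, fold assignment).
#'
#' @param outputDir where stage outputs are written.
#' @param cohort list of arguments for [cohortSpec()] (e.g.
#'   \code{list(nSubjects = 20)}).
#' @param network list: \code{fwhm} (mm, default 8), \code{fdrQ}
#'   (default 0.05), \code{inclusionThreshold} (default 1),
#'   \code{transformDialect} ("lattice48"/"interp45"), \code{nRandom}
#'   (default 5), \code{nSwapsPerEdge} (default 10), \code{nNull}
#'   (default 2000), \code{nullMethod} ("scramble"/"t").
#' @param brainAge list: \code{fwhm} (mm, default 4),
#'   \code{nComponents} (default 100), \code{folds} (default 10),
#'   \code{cost} (default 1), \code{nu} (default 0.5).
#' @param stats list: \code{splitAge} (default 70).
#' @param seed master seed.
#' @return a validated list of class \code{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig(outputDir = tempdir(),
#'                       cohort = list(nSubjects = 4))
#' @export
pipelineConfig <- function(outputDir = "sgmnet-output", cohort = list(),
                           network = list(), brainAge = list(),
                           stats = list(), seed = 1) {
  defNetwork <- list(fwhm = 8, fdrQ = 0.05, inclusionThreshold = 1,
                     transformDialect = "lattice48", nRandom = 5,
                     nSwapsPerEdge = 10, nNull = 2000,
                     nullMethod = "scramble")
  defBrainAge <- list(fwhm = 4, nComponents = 100, folds = 10, cost = 1,
                      nu = 0.5)
  defStats <- list(splitAge = 70)
  network <- utils::modifyList(defNetwork, network)
  brainAge <- utils::modifyList(defBrainAge, brainAge)
  stats <- utils::modifyList(defStats, stats)
  # normalize numeric scalars so the JSON round trip is lossless
  num <- function(l) lapply(l, function(x)
    if (is.numeric(x)) as.numeric(x) else x)
  network <- num(network)
  brainAge <- num(brainAge)
  stats <- num(stats)
  cohort <- num(cohort)
  if (network$fwhm < 0 || brainAge$fwhm < 0) stop("FWHM must be >= 0")
  if (network$fdrQ <= 0 || network$fdrQ >= 1)
    stop("'fdrQ' must lie in (0, 1)")
  if (network$inclusionThreshold < 0 || network$inclusionThreshold > 1)
    stop("'inclusionThreshold' must lie in [0, 1]")
  if (!network$transformDialect %in% c("lattice48", "interp45"))
    stop("unknown transform dialect")
  if (!network$nullMethod %in% c("scramble", "t"))
    stop("unknown null method")
  if (network$nRandom < 1) stop("'nRandom' must be >= 1")
  if (brainAge$folds < 2) stop("'folds' must be >= 2")
  structure(list(outputDir = outputDir, cohort = cohort,
                 network = network, brainAge = brainAge, stats = stats,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read / write a pipeline configuration as JSON
#'
#' The JSON round trip is lossless: \code{readPipelineConfig(
#' writePipelineConfig(cfg, path))} reproduces \code{cfg}.
#'
#' @param config a [pipelineConfig()].
#' @param path JSON file path.
#' @return \code{writePipelineConfig} returns \code{path} invisibly;
#'   \code{readPipelineConfig} returns the configuration.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipelineConfig(outputDir = x$outputDir, cohort = as.list(x$cohort),
                 network = as.list(x$network),
                 brainAge = as.list(x$brainAge),
                 stats = as.list(x$stats), seed = x$seed)
}

configHash <- function(config) {
  stringHash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA))
}

logStage <- function(stage, msg, verbose = TRUE) {
  if (verbose)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    msg))
}

#' Write a volume as NIfTI-1
#'
#' @param volume a \linkS4class{GrayMatterVolume}.
#' @param path output path (".nii" or ".nii.gz").
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@intensities)
  RNifti::pixdim(img) <- volume@voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a GrayMatterVolume
#'
#' The in-brain mask is taken as the positive voxels unless supplied.
#'
#' @param path NIfTI file.
#' @param mask optional logical array.
#' @return a \linkS4class{GrayMatterVolume}.
#' @export
readVolume <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  vs <- RNifti::pixdim(img)[1:3]
  if (is.null(mask)) mask <- a > 0
  new("GrayMatterVolume", intensities = pmax(a, 0), voxelSize = vs,
      affine = defaultAffine(vs), mask = mask)
}

#' Simulate stage: write a cohort to disk
#'
#' Generates the cohort defined by \code{config$cohort} (see
#' [cohortSpec()]) with the master seed, writes one NIfTI volume per
#' subject plus the cohort CSV, the configuration and a manifest listing
#' every file written.
#'
#' @param config a [pipelineConfig()].
#' @param verbose log progress messages.
#' @return invisibly, a list with the cohort table and file paths.
#' @export
runSimulateStage <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir <- file.path(config$outputDir, "volumes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(cohortSpec, c(config$cohort,
                                list(seed = childSeed(config$seed, 1))))
  logStage("simulate", sprintf("generating %d subjects", spec$nSubjects),
           verbose)
  coh <- simulateCohort(spec)
  files <- character(0)
  for (i in seq_len(nrow(coh$table))) {
    f <- file.path(dir, paste0(coh$table$id[i], ".nii.gz"))
    writeVolume(coh$volumes[[i]], f)
    files <- c(files, f)
  }
  cohortCsv <- file.path(config$outputDir, "cohort.csv")
  utils::write.csv(coh$table, cohortCsv, row.names = FALSE)
  cfgJson <- file.path(config$outputDir, "config.json")
  writePipelineConfig(config, cfgJson)
  manifest <- list(config_hash = configHash(config),
                   n_subjects = nrow(coh$table),
                   files = c(files, cohortCsv, cfgJson))
  jsonlite::write_json(manifest,
                       file.path(config$outputDir, "simulate_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logStage("simulate", "done", verbose)
  invisible(list(table = coh$table, volumes = coh$volumes, files = files))
}

#' Single-subject network properties
#'
#' Convenience wrapper running the whole per-subject network pipeline:
#' smoothing at the network FWHM, cube extraction, symmetry-maximized
#' similarity, FDR binarization and small-world property estimation.
#'
#' @param volume a \linkS4class{GrayMatterVolume} (unsmoothed).
#' @param fwhm network-stage smoothing, mm (default 8).
#' @param q FDR level (default 0.05).
#' @param inclusionThreshold cube inclusion threshold (default 1).
#' @param nRandom randomized references (default 5).
#' @param seed integer seed (null calibration and rewiring).
#' @param dialect transform dialect (default "lattice48").
#' @param nullMethod binarization null (default "scramble").
#' @param nNull Monte-Carlo null sample size.
#' @param nSwapsPerEdge rewiring intensity.
#' @return list with \code{cubes}, \code{similarity}, \code{network} and
#'   \code{properties}.
#' @export
subjectNetworkProperties <- function(volume, fwhm = 8, q = 0.05,
                                     inclusionThreshold = 1, nRandom = 5,
                                     seed = 1, dialect = "lattice48",
                                     nullMethod = "scramble",
                                     nNull = 2000, nSwapsPerEdge = 10) {
  if (fwhm > 0) volume <- gaussianSmooth(volume, fwhm)
  tr <- symmetryTransforms(dialect)
  cubes <- extractCubes(volume, inclusionThreshold)
  sim <- buildSimilarityMatrix(cubes, tr)
  net <- fdrBinarize(sim, q = q, nullMethod = nullMethod, cubes = cubes,
                     nNull = nNull, seed = childSeed(seed, 101),
                     transforms = tr)
  props <- smallWorldProperties(net, nRandom = nRandom,
                                seed = childSeed(seed, 202),
                                nSwapsPerEdge = nSwapsPerEdge)
  list(cubes = cubes, similarity = sim, network = net, properties = props)
}

#' Network stage: per-subject small-world properties
#'
#' Runs the network pipeline for every subject of a simulated (or
#' loaded) cohort and writes a properties CSV with one row per subject
#' (id, n_nodes, n_edges, C, L, C_rand, L_rand, gamma, lambda, sigma).
#' Optionally writes each subject's similarity matrix and adjacency in
#' Matrix Market format plus a node table CSV.
#'
#' @param config a [pipelineConfig()].
#' @param cohort result of [runSimulateStage()] (or a compatible list
#'   with \code{table} and \code{volumes}); when NULL, volumes are read
#'   from \code{config$outputDir}.
#' @param writeMatrices write per-subject .mtx / node tables (default
#'   FALSE).
#' @param verbose log progress.
#' @return the properties data.frame, invisibly also written to
#'   \code{properties.csv}.
#' @export
runNetworkStage <- function(config, cohort = NULL, writeMatrices = FALSE,
                            verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(cohort)) cohort <- loadCohort(config$outputDir)
  net <- config$network
  rows <- vector("list", nrow(cohort$table))
  for (i in seq_len(nrow(cohort$table))) {
    id <- cohort$table$id[i]
    res <- tryCatch(
      subjectNetworkProperties(
        cohort$volumes[[id]], fwhm = net$fwhm, q = net$fdrQ,
        inclusionThreshold = net$inclusionThreshold,
        nRandom = net$nRandom, seed = childSeed(config$seed, 1000 + i),
        dialect = net$transformDialect, nullMethod = net$nullMethod,
        nNull = net$nNull, nSwapsPerEdge = net$nSwapsPerEdge),
      error = function(e) stop("subject ", id, ": ", conditionMessage(e)))
    p <- res$properties
    rows[[i]] <- cbind(data.frame(id = id), as.data.frame(p),
                       n_nodes = nNodes(res$network),
                       n_edges = nEdges(res$network))
    if (writeMatrices) {
      mdir <- file.path(config$outputDir, "matrices")
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      Matrix::writeMM(Matrix::Matrix(simValues(res$similarity),
                                     sparse = TRUE),
                      file.path(mdir, paste0(id, "_similarity.mtx")))
      Matrix::writeMM(adjacency(res$network),
                      file.path(mdir, paste0(id, "_adjacency.mtx")))
      nt <- data.frame(node = seq_len(nNodes(res$cubes)),
                       gridIndex(res$cubes),
                       res$cubes@worldCenter)
      names(nt) <- c("node", "grid_i", "grid_j", "grid_k",
                     "x_mm", "y_mm", "z_mm")
      utils::write.csv(nt, file.path(mdir, paste0(id, "_nodes.csv")),
                       row.names = FALSE)
    }
    logStage("network", sprintf("%s: %d nodes, gamma %.3f", id,
                                nNodes(res$network), p@gamma), verbose)
  }
  props <- do.call(rbind, rows)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(props, file.path(config$outputDir, "properties.csv"),
                   row.names = FALSE)
  invisible(props)
}

loadCohort <- function(outputDir) {
  cohortCsv <- file.path(outputDir, "cohort.csv")
  if (!file.exists(cohortCsv))
    stop("no cohort.csv under ", outputDir, "; run the simulate stage")
  tab <- utils::read.csv(cohortCsv, stringsAsFactors = FALSE)
  vols <- lapply(tab$id, function(id)
    readVolume(file.path(outputDir, "volumes", paste0(id, ".nii.gz"))))
  names(vols) <- tab$id
  list(table = tab, volumes = vols)
}

#' Brain-age stage
#'
#' Smooths every volume at the brain-age FWHM (default 4 mm), stacks the
#' in-mask voxels, runs cross-validated PCA + SVR age prediction and
#' writes predictions.csv (id, age, predicted_age, brain_pad, fold) and
#' brainage_metrics.json (MAE, RMSE, r, folds, components, seed).
#'
#' @inheritParams runNetworkStage
#' @return the \linkS4class{BrainAgeResult}, invisibly.
#' @export
runBrainAgeStage <- function(config, cohort = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(cohort)) cohort <- loadCohort(config$outputDir)
  ba <- config$brainAge
  logStage("brainage", "smoothing and vectorizing volumes", verbose)
  sm <- lapply(cohort$volumes, gaussianSmooth, fwhm = ba$fwhm)
  X <- suppressWarnings(vectorizeVolumes(sm))
  model <- brainAgeModel(nComponents = ba$nComponents, folds = ba$folds,
                         cost = ba$cost, nu = ba$nu)
  res <- withCallingHandlers(
    fitBrainAgeCV(X, cohort$table$age, model,
                  seed = childSeed(config$seed, 7),
                  ids = cohort$table$id),
    warning = function(w) {
      logStage("brainage", conditionMessage(w), verbose)
      invokeRestart("muffleWarning")
    })
  pred <- cbind(id = cohort$table$id, as.data.frame(res))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(pred, file.path(config$outputDir, "predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(mae = res@mae, rmse = res@rmse, r = res@r, folds = res@folds,
         n_components = res@nComponents, seed = res@seed),
    file.path(config$outputDir, "brainage_metrics.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logStage("brainage", sprintf("MAE %.2f y, r %.3f", res@mae, res@r),
           verbose)
  invisible(res)
}

#' Analysis stage
#'
#' Joins the cohort table with the network properties and brain-age
#' predictions and runs [runFullAnalysis()], writing the four table
#' analogues and the run manifest (extended with the configuration hash)
#' under \code{outputDir/analysis}.
#'
#' @inheritParams runNetworkStage
#' @param properties data.frame from [runNetworkStage()]; read from disk
#'   when NULL.
#' @param predictions data.frame from [runBrainAgeStage()]; read from
#'   disk when NULL, analysis proceeds without brain age if absent.
#' @return the [runFullAnalysis()] result, invisibly.
#' @export
runAnalysisStage <- function(config, cohort = NULL, properties = NULL,
                             predictions = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(cohort)) {
    cohortCsv <- file.path(config$outputDir, "cohort.csv")
    cohort <- list(table = utils::read.csv(cohortCsv,
                                           stringsAsFactors = FALSE))
  }
  if (is.null(properties)) {
    f <- file.path(config$outputDir, "properties.csv")
    if (!file.exists(f)) stop("no properties.csv; run the network stage")
    properties <- utils::read.csv(f, stringsAsFactors = FALSE)
  }
  tab <- merge(cohort$table[, c("id", "age", "sex", "scanner")],
               properties[, c("id", "n_nodes", "gamma", "lambda",
                              "sigma")], by = "id")
  if (is.null(predictions)) {
    f <- file.path(config$outputDir, "predictions.csv")
    if (file.exists(f))
      predictions <- utils::read.csv(f, stringsAsFactors = FALSE)
  }
  if (!is.null(predictions))
    tab <- merge(tab, as.data.frame(predictions)[, c("id", "predicted_age",
                                                     "brain_pad")],
                 by = "id")
  outDir <- file.path(config$outputDir, "analysis")
  logStage("analyze", sprintf("%d subjects", nrow(tab)), verbose)
  res <- runFullAnalysis(tab, splitAge = config$stats$splitAge,
                         outDir = outDir)
  res$manifest$config_hash <- configHash(config)
  jsonlite::write_json(res$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Run the full pipeline
#'
#' simulate -> network -> brainage -> analyze, with in-memory handoff
#' between the stages (all stage outputs are still written to
#' \code{config$outputDir}). End-to-end deterministic: identical
#' configuration and seed give byte-identical CSV outputs.
#'
#' @param config a [pipelineConfig()].
#' @param verbose log progress.
#' @return list with \code{cohort} (table), \code{properties},
#'   \code{brainAge} and \code{analysis}.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  cohort <- runSimulateStage(config, verbose = verbose)
  props <- runNetworkStage(config, cohort, verbose = verbose)
  ba <- runBrainAgeStage(config, cohort, verbose = verbose)
  pred <- cbind(id = cohort$table$id, as.data.frame(ba))
  analysis <- runAnalysisStage(config, cohort, props, pred,
                               verbose = verbose)
  list(cohort = cohort$table, properties = props, brainAge = ba,
       analysis = analysis)
}
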