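#' Default pipeline configuration
#'
#' All scalar defaults are the working values of the analysis: a
#' collinearity cutoff of r = 0.8, buffer clamps of 1000 and 3000 km,
#' a 500 CDU range cut and 500 CDU overlap allowance, the top-5 /
#' 1\% / records-over-20 variable-reduction rule, 10 cross-validation
#' splits at 70/30, and 39 partial-ROC iterations at 50\% subsampling.
#' The `simulate` block drives the synthetic-data generators; replace it
#' with an `inputs` block of file paths to run on data on disk.
#'
#' @param outDir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @return a nested list; see the package vignette for the full schema.
#' @export
pipelineConfig <- function(outDir = tempfile("pipeline"), seed = 1) {
  list(
    outDir = outDir,
    seed = as.integer(seed),
    grid = list(
      originLon = 0, originLat = 1.0, nRows = 80, nCols = 80,
      cellSize = 0.01, nodata = -9999
    ),
    simulate = list(
      nLayers = 4, corrPairs = list(c(1L, 2L)), bandwidth = 8,
      truth = list(
        coefLin = c(2.5, 0, -1.5, 0), coefQuad = c(0, 0, -1, 0),
        intercept = -0.5
      ),
      bias = TRUE, biasStrength = 10,
      nOccPerSpecies = 120, nPoolRecords = 2000, nPopClusters = 8,
      climateLayers = c("env1", "env3"),
      futureSteps = list(
        step2050 = c(env1 = 0.4, env3 = 0.3),
        step2090 = c(env1 = 1.0, env3 = 0.8)
      ),
      nGcms = 7, gcmNoiseSd = 0.15, edrCutoff = 0.5
    ),
    mus = list(mu1 = c("sp1", "sp2")),
    thresholds = list(
      rMax = 0.8, maxCdu = 500, overlapCdu = 500,
      bufferMinKm = 1000, bufferMaxKm = 3000,
      topK = 5, piMin = 1, rankDivisor = 20,
      cvK = 10, trainFrac = 0.7,
      procIterations = 39, procSubsample = 0.5,
      sparseRecords = 80, nKnots = 10, beta = 1
    ),
    keepOverrides = list()
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config configuration list.
#' @param path YAML file path.
#' @return `readPipelineConfig` returns the configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  # named vectors must become YAML maps or their names are lost
  if (!is.null(config$simulate$futureSteps)) {
    config$simulate$futureSteps <- lapply(config$simulate$futureSteps, as.list)
  }
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulate$truth)) {
    cfg$simulate$truth <- lapply(cfg$simulate$truth, unlist)
  }
  cfg$simulate$futureSteps <- lapply(cfg$simulate$futureSteps, unlist)
  if (!is.null(cfg$simulate$corrPairs)) {
    cfg$simulate$corrPairs <- lapply(cfg$simulate$corrPairs, unlist)
  }
  cfg
}

#' Run the full modelling pipeline
#'
#' Sequences, per modelling unit: target-group background construction,
#' a starting model on all screened variables, permutation importance
#' averaged over cross-validation replicates, variable reduction, a
#' reduced full model, projection to current and per-GCM future
#' climates, balance thresholding and rescaling, cost-distance
#' restriction, splitting of multi-species units, SHOI, group
#' summaries, validation (cross-validation AUC, partial ROC, EDR
#' comparison) and change metrics with range-shift vectors. All outputs
#' are written under `config$outDir` and listed in a YAML manifest.
#'
#' Failures in one modelling unit are logged and do not stop the other
#' units; missing input files raise a named error before any
#' computation.
#'
#' @param config configuration list, see [pipelineConfig()].
#' @param quiet suppress progress messages.
#' @return the manifest (invisibly also written to
#'   `outDir/manifest.yaml`).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  checkConfig(config)
  thr <- config$thresholds
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  spec <- with(config$grid, GridSpec(
    originLon, originLat, nRows, nCols, cellSize, nodata
  ))
  say("assembling inputs")
  inp <- if (!is.null(config$inputs)) {
    loadInputs(config, spec)
  } else {
    simulateInputs(config, spec)
  }
  stack <- inp$stack
  pop <- inp$pop
  allOccs <- inp$occs
  edr <- inp$edr

  manifest <- list(
    seed = config$seed, created = "run",
    parameters = thr, outputs = list(), failures = list()
  )
  envMatrixAt <- function(cells) {
    X <- vapply(stack, function(g) g@values[as.matrix(cells[, c("row", "col")])],
      numeric(nrow(cells))
    )
    matrix(X, ncol = length(stack), dimnames = list(NULL, names(stack)))
  }
  speciesOutputs <- list()

  for (muId in names(config$mus)) {
    res <- tryCatch(
      runMu(
        muId, config$mus[[muId]], spec, stack, pop, allOccs, edr,
        thr, config, outDir, envMatrixAt, say
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      say("MU %s failed: %s", muId, conditionMessage(res))
      manifest$failures[[muId]] <- conditionMessage(res)
      next
    }
    manifest$outputs[[muId]] <- res$files
    speciesOutputs <- c(speciesOutputs, res$species)
  }

  if (length(speciesOutputs)) {
    say("global summaries")
    suits <- lapply(speciesOutputs, `[[`, "suit")
    shois <- lapply(speciesOutputs, `[[`, "shoi")
    paths <- c(
      richness = "summary_richness.asc",
      cumulative_suitability = "summary_cumulative_suitability.asc",
      cumulative_shoi = "summary_cumulative_shoi.asc"
    )
    writeAsciiGrid(richness(suits), file.path(outDir, paths["richness"]))
    writeAsciiGrid(
      groupSummary(suits, "sum"),
      file.path(outDir, paths["cumulative_suitability"])
    )
    writeAsciiGrid(
      groupSummary(shois, "sum"),
      file.path(outDir, paths["cumulative_shoi"])
    )
    manifest$outputs$summaries <- as.list(paths)
  }
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}

checkConfig <- function(config) {
  for (f in c("outDir", "seed", "grid", "mus", "thresholds")) {
    if (is.null(config[[f]])) stop("config is missing field: ", f, call. = FALSE)
  }
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config needs either a 'simulate' or an 'inputs' block", call. = FALSE)
  if (!is.null(config$inputs)) {
    for (f in c("rasters", "population", "occurrences")) {
      if (is.null(config$inputs[[f]]))
        stop("config inputs block is missing field: ", f, call. = FALSE)
      for (p in unlist(config$inputs[[f]])) {
        if (!file.exists(p))
          stop("input file for '", f, "' not found: ", p, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

loadInputs <- function(config, spec) {
  rasters <- lapply(config$inputs$rasters, readAsciiGrid)
  occs <- readOccurrences(config$inputs$occurrences, spec)
  edr <- if (!is.null(config$inputs$edr)) readGeoJSON(config$inputs$edr) else NULL
  list(
    stack = rasters, pop = readAsciiGrid(config$inputs$population),
    occs = occs, edr = edr, futures = NULL
  )
}

simulateInputs <- function(config, spec) {
  sim <- config$simulate
  seed <- config$seed
  stack <- genEnvStack(spec, sim$nLayers,
    corrPairs = sim$corrPairs,
    bandwidth = sim$bandwidth, seed = seed
  )
  truth <- TruthModel(sim$truth$coefLin, sim$truth$coefQuad, sim$truth$intercept)
  truthGrid <- genTrueSuitability(stack, truth)
  bias <- if (isTRUE(sim$bias)) genBiasField(spec, sim$biasStrength) else NULL
  allSpecies <- unique(unlist(config$mus))
  occList <- lapply(seq_along(allSpecies), function(i) {
    genOccurrences(truthGrid, sim$nOccPerSpecies, bias,
      seed = seed + 1000L + i, species = allSpecies[i]
    )
  })
  # target-group pool: records of other snake taxa, distributed like the
  # sampling effort itself (truth surface constant), so the background
  # carries the same bias as the presences
  if (!is.null(sim$nPoolRecords) && sim$nPoolRecords > 0) {
    ones <- GeoGrid(spec, 1)
    occList <- c(occList, list(genOccurrences(ones, sim$nPoolRecords, bias,
      seed = seed + 999L, species = "tg_pool"
    )))
  }
  df <- do.call(rbind, lapply(occList, occRecords))
  occs <- snapOccurrences(
    OccurrenceSet(df$species, df$lon, df$lat, df$uncertainty_m), spec
  )
  pop <- genPopulation(spec, sim$nPopClusters, seed = seed + 2000L)
  futures <- lapply(seq_along(sim$futureSteps), function(k) {
    genFutureStacks(stack, sim$futureSteps[[k]],
      nGcms = sim$nGcms,
      seed = seed + 3000L + k, noiseSd = sim$gcmNoiseSd
    )
  })
  names(futures) <- names(sim$futureSteps)
  list(
    stack = stack, pop = pop, occs = occs,
    edr = genEdr(truthGrid, sim$edrCutoff),
    futures = futures, truthGrid = truthGrid
  )
}

# model one MU end to end; returns output file list + per-species grids
runMu <- function(muId, members, spec, stack, pop, allOccs, edr, thr,
                  config, outDir, envMatrixAt, say) {
  say("MU %s: background and screening", muId)
  keep <- allOccs@species %in% members
  muOccs <- OccurrenceSet(
    allOccs@species[keep], allOccs@lon[keep],
    allOccs@lat[keep], allOccs@uncertainty[keep]
  )
  muOccs <- filterByAccuracy(muOccs)
  if (length(muOccs) < 10) stop("too few occurrences for MU ", muId)
  width <- computeBuffer(muOccs, thr$bufferMinKm, thr$bufferMaxKm)
  bg <- buildBackground(allOccs, muOccs, width, spec)

  presCells <- as.data.frame(cellOf(spec, muOccs@lon, muOccs@lat))
  presX <- envMatrixAt(presCells)
  bgX <- envMatrixAt(bg$cells)
  okP <- stats::complete.cases(presX)
  okB <- stats::complete.cases(bgX)
  presX <- presX[okP, , drop = FALSE]
  bgX <- bgX[okB, , drop = FALSE]

  vars1 <- collinearityFilter(as.data.frame(bgX),
    rMax = thr$rMax,
    keepOverrides = config$keepOverrides
  )
  allowProd <- !(nrow(presX) < thr$sparseRecords && width <= thr$bufferMinKm)
  fitArgs <- list(
    allowProduct = allowProd, nKnots = thr$nKnots, beta = thr$beta
  )
  say("MU %s: starting models and permutation importance", muId)
  cvStart <- cvWithImportance(
    presX[, vars1, drop = FALSE], bgX[, vars1, drop = FALSE],
    k = thr$cvK, trainFrac = thr$trainFrac, seed = config$seed + 17L,
    fitArgs = fitArgs
  )
  vars2 <- reduceVariables(cvStart$importance, nrow(presX),
    topK = thr$topK, piMin = thr$piMin, rankDivisor = thr$rankDivisor
  )
  say("MU %s: reduced model (%d vars)", muId, length(vars2))
  cvAUC <- crossValidate(
    presX[, vars2, drop = FALSE], bgX[, vars2, drop = FALSE],
    k = thr$cvK, trainFrac = thr$trainFrac, seed = config$seed + 29L,
    allowProduct = allowProd, nKnots = thr$nKnots, beta = thr$beta
  )
  model <- fitNicheModel(
    presX[, vars2, drop = FALSE], bgX[, vars2, drop = FALSE],
    allowProduct = allowProd, nKnots = thr$nKnots, beta = thr$beta
  )
  model@cvAUC <- cvAUC
  model@importance <- cvStart$importance

  say("MU %s: projection and post-processing", muId)
  rawSuit <- maskToExtent(predictSuitability(model, stack), bg$extent)
  suitThr <- thresholdAndRescale(rawSuit, model@threshold)
  costMu <- costDistance(rawSuit, muOccs)
  clip <- clipByCdu(suitThr, costMu, thr$maxCdu)
  perSpCost <- lapply(members, function(sp) {
    idx <- muOccs@species == sp
    costDistance(rawSuit, OccurrenceSet(
      muOccs@species[idx], muOccs@lon[idx], muOccs@lat[idx],
      muOccs@uncertainty[idx]
    ))
  })
  names(perSpCost) <- members
  spSuits <- splitMu(clip$clipped, perSpCost,
    overlapCdu = thr$overlapCdu,
    threshold = model@threshold
  )

  muDir <- file.path(outDir, muId)
  dir.create(muDir, showWarnings = FALSE)
  files <- list()
  wr <- function(grid, name) {
    p <- file.path(muId, paste0(name, ".asc"))
    writeAsciiGrid(grid, file.path(outDir, p))
    files[[name]] <<- p
    p
  }
  wr(rawSuit, "suitability_raw")
  wr(clip$clipped, "suitability_clipped")
  wr(costMu, "cost_distance")

  say("MU %s: validation", muId)
  proc <- partialRoc(rawSuit, muOccs,
    nIter = thr$procIterations,
    subsampleFrac = thr$procSubsample, seed = config$seed + 41L
  )
  valid <- data.frame(
    mu = muId, meanCvAUC = mean(cvAUC), minCvAUC = min(cvAUC),
    procMeanRatio = proc$meanRatio, procP = proc$p
  )
  if (!is.null(edr)) {
    cmp <- edrCompare(clip$clipped, edr)
    valid <- cbind(valid, as.data.frame(as.list(cmp)))
  }
  writeStableCsv(valid, file.path(outDir, muId, "validation.csv"))
  files[["validation"]] <- file.path(muId, "validation.csv")

  say("MU %s: futures and change metrics", muId)
  speciesOut <- list()
  changeRows <- list()
  vecRows <- list()
  futures <- if (is.null(config$inputs)) {
    simFuturesFor(config, spec, stack)
  } else {
    NULL
  }
  for (sp in members) {
    spShoi <- shoi(spSuits[[sp]], pop)
    wr(spSuits[[sp]], paste0("suitability_", sp))
    wr(spShoi, paste0("shoi_", sp))
    speciesOut[[sp]] <- list(suit = spSuits[[sp]], shoi = spShoi)
  }
  if (!is.null(futures)) {
    for (stepName in names(futures)) {
      projs <- lapply(futures[[stepName]], function(fs) {
        maskToExtent(predictSuitability(model, fs), bg$extent)
      })
      gs <- summarizeGcms(projs)
      for (qn in c("q10", "median", "q90")) {
        futThr <- thresholdAndRescale(gs[[qn]], model@threshold)
        futShoi <- shoi(futThr, pop)
        if (qn == "median") {
          wr(futThr, paste0("suitability_", stepName, "_median"))
        }
        cm <- changeMetrics(suitThr, futThr, shoi(suitThr, pop), futShoi)
        changeRows[[paste(stepName, qn)]] <- data.frame(
          mu = muId, step = stepName, quantile = qn,
          as.data.frame(cm)
        )
        if (qn == "median") {
          vec <- shiftVector(rangeCentroid(suitThr), rangeCentroid(futThr))
          vecRows[[stepName]] <- data.frame(
            mu = muId, step = stepName,
            D1_m = vec[["D1_m"]], D2_deg = vec[["D2_deg"]]
          )
        }
      }
    }
    writeStableCsv(
      do.call(rbind, changeRows),
      file.path(outDir, muId, "change_metrics.csv")
    )
    writeStableCsv(
      do.call(rbind, vecRows),
      file.path(outDir, muId, "shift_vectors.csv")
    )
    files[["change_metrics"]] <- file.path(muId, "change_metrics.csv")
    files[["shift_vectors"]] <- file.path(muId, "shift_vectors.csv")
  }
  list(files = files, species = speciesOut)
}

# future stacks are regenerated deterministically from the master seed
# so per-MU runs stay independent
simFuturesFor <- function(config, spec, stack) {
  sim <- config$simulate
  futures <- lapply(seq_along(sim$futureSteps), function(k) {
    genFutureStacks(stack, sim$futureSteps[[k]],
      nGcms = sim$nGcms,
      seed = config$seed + 3000L + k, noiseSd = sim$gcmNoiseSd
    )
  })
  names(futures) <- names(sim$futureSteps)
  futures
}

maskToExtent <- function(grid, extent) {
  cc <- cellCenters(grid@spec)
  outside <- cc$lon < extent["west"] | cc$lon > extent["east"] |
    cc$lat < extent["south"] | cc$lat > extent["north"]
  v <- grid@values
  v[matrix(outside, nrow(v), ncol(v))] <- NA
  GeoGrid(grid@spec, v)
}

# fixed-format CSV so identical results are bit-identical on disk
writeStableCsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

# cross-validated fits: test AUCs plus permutation importance averaged
# over the replicates
cvWithImportance <- function(presX, bgX, k, trainFrac, seed, fitArgs) {
  n <- nrow(presX)
  nTrain <- floor(trainFrac * n)
  if (nTrain < 2 || nTrain >= n) stop("too few presences to split", call. = FALSE)
  set.seed(seed)
  aucs <- numeric(k)
  imps <- NULL
  for (i in seq_len(k)) {
    idx <- sample.int(n, nTrain)
    fit <- do.call(fitNicheModel, c(
      list(
        presX = presX[idx, , drop = FALSE], bgX = bgX,
        computeThreshold = FALSE
      ), fitArgs
    ))
    aucs[i] <- aucScore(
      predictSuitability(fit, presX[-idx, , drop = FALSE]),
      predictSuitability(fit, bgX)
    )
    imp <- permutationImportance(fit, presX[idx, , drop = FALSE], bgX,
      nPerm = 1, seed = seed + i
    )
    imps <- if (is.null(imps)) imp else imps + imp
  }
  list(auc = aucs, importance = imps / k)
}
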