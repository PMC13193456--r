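#' Synthetic pipeline inputs with known ground truth
#'
#' These generators stand in for real occurrence databases, environmental
#' layers, human population rasters and expert-derived range polygons.
#' They produce spatially autocorrelated environmental fields (smoothed
#' Gaussian noise), a known logistic "true suitability" surface,
#' presence points sampled proportional to suitability times a sampling
#' bias field, clustered lognormal population density, per-GCM future
#' perturbations and range polygons traced from the truth surface. All
#' generators are deterministic given their seed.
#'
#' @name synthetic-data
NULL

# separable Gaussian smoothing with replicate padding
gaussianSmooth <- function(m, bandwidth) {
  half <- max(1L, ceiling(3 * bandwidth))
  k <- stats::dnorm(seq(-half, half), sd = bandwidth)
  k <- k / sum(k)
  smooth1 <- function(x) {
    padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
    stats::convolve(padded, rev(k), type = "filter")
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

#' Generate a stack of spatially autocorrelated environmental layers
#'
#' Each layer is white noise passed through a Gaussian filter (giving
#' controllable spatial autocorrelation), then standardized to mean 0,
#' sd 1. Pairs listed in `corrPairs` are made strongly collinear by
#' constructing the second member as the first plus a small amount of
#' independent smoothed noise, so the collinearity filter downstream is
#' exercised (empirical |r| > 0.8).
#'
#' @param spec a [GridSpec-class].
#' @param nLayers number of layers (>= 1).
#' @param corrPairs list of 2-element integer vectors (1-based layer
#'   indices); the second layer of each pair is rebuilt collinear to the
#'   first.
#' @param bandwidth Gaussian filter bandwidth in cells (default 8).
#' @param seed integer seed.
#' @return named list of [GeoGrid-class] layers (`env1`, `env2`, ...).
#' @examples
#' stack <- genEnvStack(GridSpec(0, 1, 40, 40), 3,
#'   corrPairs = list(c(1, 2)), seed = 1)
#' cor(as.vector(gridValues(stack[[1]])), as.vector(gridValues(stack[[2]])))
#' @export
genEnvStack <- function(spec, nLayers, corrPairs = list(), bandwidth = 8,
                        seed = 1) {
  if (nLayers < 1) stop("nLayers must be >= 1", call. = FALSE)
  set.seed(seed)
  nr <- spec@nRows
  nc <- spec@nCols
  mk <- function() {
    z <- gaussianSmooth(matrix(stats::rnorm(nr * nc), nr, nc), bandwidth)
    (z - mean(z)) / stats::sd(z)
  }
  layers <- lapply(seq_len(nLayers), function(i) mk())
  for (pr in corrPairs) {
    i <- pr[1]; j <- pr[2]
    # additive independent noise with sd 0.5 gives r = 1/sqrt(1.25) ~ 0.89
    z <- layers[[i]] + 0.5 * mk()
    layers[[j]] <- (z - mean(z)) / stats::sd(z)
  }
  out <- lapply(layers, function(m) GeoGrid(spec, m))
  names(out) <- paste0("env", seq_len(nLayers))
  out
}

#' TruthModel: parameters of the known suitability surface
#'
#' @param coefLin,coefQuad per-layer coefficients of linear and quadratic
#'   terms (quadratic defaults to all zero).
#' @param intercept scalar intercept.
#' @return a list of class `TruthModel`.
#' @export
TruthModel <- function(coefLin, coefQuad = rep(0, length(coefLin)),
                       intercept = 0) {
  stopifnot(length(coefQuad) == length(coefLin))
  structure(
    list(coefLin = coefLin, coefQuad = coefQuad, intercept = intercept),
    class = "TruthModel"
  )
}

#' True suitability surface from a layer stack and a TruthModel
#'
#' Suitability is the logistic transform of a linear-plus-quadratic
#' combination of the layers, so it always lies in \\[0, 1\\].
#'
#' @param stack named list of aligned [GeoGrid-class] layers.
#' @param truth a [TruthModel()].
#' @return a [GeoGrid-class] of true suitability.
#' @export
genTrueSuitability <- function(stack, truth) {
  if (length(stack) != length(truth$coefLin))
    stop("stack has ", length(stack), " layers but truth model has ",
      length(truth$coefLin), " coefficients", call. = FALSE)
  for (g in stack[-1]) stopIfMisaligned(stack[[1]], g)
  eta <- truth$intercept
  for (k in seq_along(stack)) {
    v <- stack[[k]]@values
    eta <- eta + truth$coefLin[k] * v + truth$coefQuad[k] * v^2
  }
  GeoGrid(stack[[1]]@spec, 1 / (1 + exp(-eta)))
}

#' Sample presence points proportional to suitability times bias
#'
#' Cells are drawn with replacement with probability proportional to
#' `truth * bias`; each draw is jittered uniformly within its cell and
#' assigned a lognormal positional uncertainty (median 100 m by
#' default), which exercises the accuracy filter downstream.
#'
#' @param truthGrid true suitability [GeoGrid-class].
#' @param n number of records.
#' @param biasGrid sampling-bias [GeoGrid-class] aligned with
#'   `truthGrid`; `NULL` for uniform sampling effort.
#' @param seed integer seed.
#' @param species species id attached to the records.
#' @param uncMeanlog,uncSdlog lognormal uncertainty parameters (meters).
#' @return an [OccurrenceSet-class] (not yet deduplicated per cell).
#' @export
genOccurrences <- function(truthGrid, n, biasGrid = NULL, seed = 1,
                           species = "sp1", uncMeanlog = log(100),
                           uncSdlog = 0.75) {
  if (n == 0) return(OccurrenceSet())
  spec <- truthGrid@spec
  w <- as.vector(truthGrid@values)
  if (!is.null(biasGrid)) {
    stopIfMisaligned(truthGrid, biasGrid)
    w <- w * as.vector(biasGrid@values)
  }
  w[is.na(w)] <- 0
  if (all(w <= 0)) stop("sampling surface is identically zero", call. = FALSE)
  set.seed(seed)
  cells <- sample.int(length(w), n, replace = TRUE, prob = w)
  row <- (cells - 1L) %% spec@nRows + 1L
  col <- (cells - 1L) %/% spec@nRows + 1L
  cc <- coordOf(spec, row, col)
  cs <- spec@cellSize
  lon <- cc[, 1] + stats::runif(n, -cs / 2, cs / 2) * 0.999
  lat <- cc[, 2] + stats::runif(n, -cs / 2, cs / 2) * 0.999
  unc <- stats::rlnorm(n, uncMeanlog, uncSdlog)
  OccurrenceSet(species, lon, lat, unc)
}

#' Sampling-bias field with a road-like gradient
#'
#' Effort decays smoothly with distance from a diagonal "road" across
#' the grid, mimicking accessibility-driven sampling bias.
#'
#' @param spec a [GridSpec-class].
#' @param strength ratio of maximum to minimum effort (default 10).
#' @return a [GeoGrid-class] of relative sampling effort in (0, 1].
#' @export
genBiasField <- function(spec, strength = 10) {
  nr <- spec@nRows
  nc <- spec@nCols
  ri <- matrix(seq_len(nr) / nr, nr, nc)
  ci <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  d <- abs(ri - ci) / sqrt(2) # distance to the main diagonal, normalized
  eff <- exp(-d * log(strength) / 0.35)
  GeoGrid(spec, pmax(eff, 1 / strength))
}

#' Clustered lognormal human population density
#'
#' A low lognormal background with `nClusters` Gaussian hotspots of
#' lognormal amplitude, emulating people-per-grid-cell layers: most
#' cells near zero, towns and cities orders of magnitude denser.
#'
#' @param spec a [GridSpec-class].
#' @param nClusters number of hotspots (>= 0).
#' @param seed integer seed.
#' @param background median background density (people per cell).
#' @return a [GeoGrid-class] of non-negative density.
#' @export
genPopulation <- function(spec, nClusters = 10, seed = 1, background = 2) {
  set.seed(seed)
  nr <- spec@nRows
  nc <- spec@nCols
  dens <- matrix(stats::rlnorm(nr * nc, log(background), 0.5), nr, nc)
  if (nClusters > 0) {
    ri <- matrix(seq_len(nr), nr, nc)
    ci <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    cy <- stats::runif(nClusters, 1, nr)
    cx <- stats::runif(nClusters, 1, nc)
    amp <- stats::rlnorm(nClusters, log(500), 1)
    sd <- stats::runif(nClusters, 0.02, 0.06) * max(nr, nc)
    for (k in seq_len(nClusters)) {
      dens <- dens + amp[k] * exp(-((ri - cy[k])^2 + (ci - cx[k])^2) /
        (2 * sd[k]^2))
    }
  }
  GeoGrid(spec, dens)
}

#' Per-GCM future climate stacks
#'
#' Each GCM perturbs the designated climate layers by a prescribed mean
#' delta plus GCM-specific smoothed noise; all other layers are held
#' constant across time steps.
#'
#' @param stack named list of current-condition layers.
#' @param deltas named numeric vector of mean shifts for the climate
#'   layers (names must be layer names); layers not named are constant.
#' @param nGcms number of GCMs (>= 1, the study used 7).
#' @param seed integer seed.
#' @param noiseSd sd of the smoothed GCM-specific noise (0 = none).
#' @param bandwidth smoothing bandwidth of the noise field, cells.
#' @return list of `nGcms` stacks (each a named list of GeoGrids).
#' @export
genFutureStacks <- function(stack, deltas, nGcms = 7, seed = 1,
                            noiseSd = 0.1, bandwidth = 8) {
  if (nGcms < 1) stop("nGcms must be >= 1", call. = FALSE)
  if (is.null(names(deltas)) || !all(names(deltas) %in% names(stack)))
    stop("deltas must be named after layers in the stack", call. = FALSE)
  set.seed(seed)
  nr <- nRows(stack[[1]])
  nc <- nCols(stack[[1]])
  lapply(seq_len(nGcms), function(g) {
    out <- stack
    for (nm in names(deltas)) {
      pert <- deltas[[nm]]
      if (noiseSd > 0) {
        z <- gaussianSmooth(matrix(stats::rnorm(nr * nc), nr, nc), bandwidth)
        pert <- pert + noiseSd * (z - mean(z)) / stats::sd(z)
      }
      out[[nm]] <- GeoGrid(stack[[nm]]@spec, stack[[nm]]@values + pert)
    }
    out
  })
}

#' Expert-derived range polygons traced from the truth surface
#'
#' Cells with truth at or above the cutoff are collected into
#' rectangular row runs and emitted as a polygon set, the synthetic
#' stand-in for hand-drawn expert range maps. Rasterizing the result on
#' the same lattice recovers exactly the cutoff cell set.
#'
#' @param truthGrid [GeoGrid-class] of true suitability.
#' @param cutoff inclusion threshold in \\[0, 1.01\\].
#' @return a polygon set as in [writeGeoJSON()] (empty list if no cell
#'   qualifies).
#' @export
genEdr <- function(truthGrid, cutoff) {
  if (cutoff < 0 || cutoff > 1.01)
    stop("cutoff must be in [0, 1.01]", call. = FALSE)
  spec <- truthGrid@spec
  v <- truthGrid@values
  cs <- spec@cellSize
  polys <- list()
  for (i in seq_len(spec@nRows)) {
    inRow <- which(!is.na(v[i, ]) & v[i, ] >= cutoff)
    if (!length(inRow)) next
    runs <- split(inRow, cumsum(c(1, diff(inRow) != 1)))
    north <- spec@originLat - (i - 1) * cs
    south <- spec@originLat - i * cs
    for (run in runs) {
      west <- spec@originLon + (min(run) - 1) * cs
      east <- spec@originLon + max(run) * cs
      ring <- rbind(
        c(west, south), c(east, south), c(east, north),
        c(west, north), c(west, south)
      )
      polys[[length(polys) + 1L]] <- list(ring)
    }
  }
  polys
}
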