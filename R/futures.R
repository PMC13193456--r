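#' Summarize projections across a GCM ensemble
#'
#' Cellwise median (most likely), 10\% quantile (minimum likely) and
#' 90\% quantile (maximum likely) across per-GCM suitability grids,
#' using the linear-interpolation quantile.
#'
#' @param grids list of >= 2 aligned [GeoGrid-class] projections (one
#'   per GCM).
#' @return list with `median`, `q10`, `q90` grids and `nGcms`.
#' @export
summarizeGcms <- function(grids) {
  if (length(grids) < 2) stop("need at least 2 GCM grids", call. = FALSE)
  for (g in grids[-1]) stopIfMisaligned(grids[[1]], g)
  spec <- grids[[1]]@spec
  vals <- vapply(grids, function(g) as.vector(g@values),
    numeric(spec@nRows * spec@nCols)
  )
  qs <- apply(vals, 1, stats::quantile,
    probs = c(0.1, 0.5, 0.9),
    type = 7, names = FALSE, na.rm = FALSE
  )
  toGrid <- function(x) GeoGrid(spec, matrix(x, spec@nRows, spec@nCols))
  list(
    median = toGrid(qs[2, ]), q10 = toGrid(qs[1, ]), q90 = toGrid(qs[3, ]),
    nGcms = length(grids)
  )
}

#' Range and overlap change metrics between two time steps
#'
#' Grids are expected thresholded (suitable means value > 0). Expansion
#' counts newly suitable cells, contraction newly unsuitable cells, so
#' future range size = current size + expansion - contraction. Total
#' suitability and total SHOI are sums over suitable cells.
#'
#' @param current,future thresholded suitability grids.
#' @param shoiCurrent,shoiFuture optional matching SHOI grids.
#' @return named list of scalar metrics.
#' @export
changeMetrics <- function(current, future, shoiCurrent = NULL,
                          shoiFuture = NULL) {
  stopIfMisaligned(current, future)
  cv <- current@values
  fv <- future@values
  curOn <- !is.na(cv) & cv > 0
  futOn <- !is.na(fv) & fv > 0
  out <- list(
    rangeCurrent = sum(curOn),
    rangeFuture = sum(futOn),
    expansion = sum(futOn & !curOn),
    contraction = sum(curOn & !futOn),
    totalSuitCurrent = sum(cv[curOn]),
    totalSuitFuture = sum(fv[futOn])
  )
  if (!is.null(shoiCurrent)) {
    stopIfMisaligned(current, shoiCurrent)
    out$totalShoiCurrent <- sum(shoiCurrent@values[curOn], na.rm = TRUE)
  }
  if (!is.null(shoiFuture)) {
    stopIfMisaligned(future, shoiFuture)
    out$totalShoiFuture <- sum(shoiFuture@values[futOn], na.rm = TRUE)
  }
  out
}

#' Centroid of the suitable range
#'
#' The unweighted arithmetic mean of the cell-center coordinates of all
#' suitable cells (value > 0). Computed on unprojected lon/lat means,
#' which is what range-shift vectors are defined on (metric distortion
#' at high latitude is accepted).
#'
#' @param suit a thresholded suitability [GeoGrid-class].
#' @return named vector `c(lon, lat)` in degrees.
#' @export
rangeCentroid <- function(suit) {
  v <- suit@values
  on <- which(!is.na(v) & v > 0, arr.ind = TRUE)
  if (nrow(on) == 0) stop("no suitable cell; centroid undefined", call. = FALSE)
  xy <- coordOf(suit@spec, on[, 1], on[, 2])
  c(lon = mean(xy[, 1]), lat = mean(xy[, 2]))
}

EARTH_RADIUS_M <- 6371000

#' Range-shift vector between two centroids
#'
#' Distance is the great-circle (haversine) distance on a sphere of
#' radius 6,371,000 m; direction is the initial bearing in degrees from
#' the current to the future centroid, in (-180, 180] with 0 = north,
#' 90 = east.
#'
#' @param cNow,cFuture centroids as `c(lon, lat)` in degrees (see
#'   [rangeCentroid()]).
#' @return named vector `c(D1_m, D2_deg)`: shift distance in meters and
#'   bearing in degrees.
#' @examples
#' shiftVector(c(lon = 0, lat = 0), c(lon = 1, lat = 0)) # ~111.2 km east
#' @export
shiftVector <- function(cNow, cFuture) {
  lat1 <- cNow[["lat"]] * pi / 180
  lat2 <- cFuture[["lat"]] * pi / 180
  dLat <- lat2 - lat1
  dLon <- (cFuture[["lon"]] - cNow[["lon"]]) * pi / 180
  a <- sin(dLat / 2)^2 + cos(lat1) * cos(lat2) * sin(dLon / 2)^2
  d1 <- EARTH_RADIUS_M * 2 * atan2(sqrt(a), sqrt(1 - a))
  d2 <- (180 / pi) * atan2(
    sin(dLon) * cos(lat2),
    cos(lat1) * sin(lat2) - sin(lat1) * cos(lat2) * cos(dLon)
  )
  c(D1_m = d1, D2_deg = d2)
}

#' Circular median of a set of bearings
#'
#' The bearing minimizing the summed circular distance to the data
#' (candidates are the data angles and all pairwise circular midpoints;
#' among ties the circular mean of the minimizers is returned, so e.g.
#' bearings 350 and 10 degrees give 0).
#'
#' @param deg bearings in degrees.
#' @return median bearing in degrees, in (-180, 180].
#' @export
circularMedian <- function(deg) {
  if (!length(deg)) stop("no bearings", call. = FALSE)
  th <- deg %% 360
  circDist <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  mids <- outer(th, th, function(a, b) (a + (((b - a + 180) %% 360) - 180) / 2) %% 360)
  cand <- unique(c(th, as.vector(mids)))
  obj <- vapply(cand, function(c0) sum(circDist(c0, th)), 0)
  best <- cand[obj <= min(obj) + 1e-9]
  rad <- best * pi / 180
  med <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  if (med <= -180) med <- med + 360
  med
}

#' Per-region median range-shift vectors
#'
#' Summarizes individual species' shift vectors by biogeographic
#' region: the circular median of bearings and the median of shift
#' lengths. Regions with no vectors are skipped with a warning.
#'
#' @param vectors data.frame with columns `D1_m` and `D2_deg` (one row
#'   per species).
#' @param regions character vector of region labels, one per row.
#' @return data.frame with `region`, `n`, `D1_m` (median length) and
#'   `D2_deg` (circular median bearing).
#' @export
regionalShiftSummary <- function(vectors, regions) {
  stopifnot(nrow(vectors) == length(regions))
  out <- lapply(unique(regions), function(rg) {
    idx <- which(regions == rg)
    if (!length(idx)) {
      warning("region with no vectors skipped: ", rg)
      return(NULL)
    }
    data.frame(
      region = rg, n = length(idx),
      D1_m = stats::median(vectors$D1_m[idx]),
      D2_deg = circularMedian(vectors$D2_deg[idx]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}
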