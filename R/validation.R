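#' Rank-based AUC of presence vs background scores
#'
#' The probability that a randomly chosen presence outscores a randomly
#' chosen background point, with ties counting one half (the
#' Mann-Whitney statistic).
#'
#' @param presScores,bgScores numeric score vectors (each non-empty).
#' @return AUC in \\[0, 1\\].
#' @export
aucScore <- function(presScores, bgScores) {
  if (!length(presScores) || !length(bgScores))
    stop("need at least one score in each group", call. = FALSE)
  r <- rank(c(presScores, bgScores))
  np <- length(presScores)
  nb <- length(bgScores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Partial ROC evaluation of a suitability surface
#'
#' Compares the omission-area curve of observed occurrences to that of
#' random points. Per iteration, half of the occurrences are subsampled
#' and the same number of random data cells drawn; for predicted-area
#' fractions from 1\% to 100\% (thresholds taken at every 1\% of
#' predicted area over descending suitability) the curve of
#' (fractional predicted area, 1 - omission) is integrated by the
#' trapezoid rule for both point sets, and their ratio recorded. Ratios
#' above 1 mean occurrences fall in high-suitability area more than
#' random points do; the p-value is the fraction of iterations with
#' ratio <= 1 (one-sided test against chance performance).
#'
#' @param suit suitability [GeoGrid-class] (constant grids are
#'   degenerate and raise an error).
#' @param occs an [OccurrenceSet-class] with >= 4 records on the grid.
#' @param nIter iterations (default 39).
#' @param subsampleFrac occurrence fraction per iteration (default 0.5).
#' @param seed integer seed.
#' @return list with `ratios` (length `nIter`), `meanRatio` and `p`.
#' @export
partialRoc <- function(suit, occs, nIter = 39, subsampleFrac = 0.5, seed = 1) {
  v <- as.vector(suit@values)
  ok <- which(!is.na(v))
  if (length(unique(v[ok])) < 2)
    stop("constant suitability grid: partial ROC ratio undefined", call. = FALSE)
  rc <- cellOf(suit@spec, occs@lon, occs@lat)
  cells <- (rc[, 2] - 1L) * suit@spec@nRows + rc[, 1]
  cells <- cells[!is.na(cells)]
  cells <- cells[!is.na(v[cells])]
  if (length(cells) < 4) stop("need at least 4 occurrences on the grid", call. = FALSE)
  occVals <- v[cells]

  areaFracs <- seq(0.01, 1, by = 0.01)
  # threshold at each predicted-area fraction: value of the descending
  # suitability order statistic closest to that area
  sorted <- sort(v[ok], decreasing = TRUE)
  thr <- sorted[pmax(1L, ceiling(areaFracs * length(sorted)))]
  curveAuc <- function(vals) {
    sens <- vapply(thr, function(t) mean(vals >= t), 0)
    x <- c(0, areaFracs)
    y <- c(0, sens)
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  nSub <- max(1L, round(subsampleFrac * length(occVals)))
  set.seed(seed)
  ratios <- vapply(seq_len(nIter), function(i) {
    obs <- occVals[sample.int(length(occVals), nSub)]
    rnd <- v[sample(ok, nSub, replace = TRUE)]
    curveAuc(obs) / curveAuc(rnd)
  }, 0)
  list(ratios = ratios, meanRatio = mean(ratios), p = mean(ratios <= 1))
}

#' Compare a thresholded model against an expert-derived range
#'
#' Commission is the percentage of suitable cells falling outside the
#' EDR (overprediction), congruence the percentage inside (agreement
#' with expert opinion) — the two sum to 100. Omission is the
#' percentage of EDR cells the model leaves unsuitable
#' (underprediction).
#'
#' @param suit thresholded suitability [GeoGrid-class] (suitable means
#'   value > 0).
#' @param edr polygon set (see [writeGeoJSON()]) or a 0/1
#'   [GeoGrid-class] mask.
#' @return named vector `c(omission, commission, congruence)` in
#'   percent.
#' @export
edrCompare <- function(suit, edr) {
  mask <- if (methods::is(edr, "GeoGrid")) edr else rasterizePolygons(edr, suit@spec)
  stopIfMisaligned(suit, mask)
  sv <- suit@values
  on <- !is.na(sv) & sv > 0
  inEdr <- !is.na(mask@values) & mask@values > 0
  if (!any(inEdr)) stop("empty EDR: omission undefined", call. = FALSE)
  nSuit <- sum(on)
  commission <- if (nSuit) 100 * sum(on & !inEdr) / nSuit else 0
  congruence <- if (nSuit) 100 * sum(on & inEdr) / nSuit else 100
  omission <- 100 * sum(inEdr & !on) / sum(inEdr)
  c(omission = omission, commission = commission, congruence = congruence)
}
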