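KM_PER_DEG <- 6371000 * pi / 180 / 1000 # ~111.195 km, Earth radius 6,371,000 m

#' Buffer width for a modelling unit's target-group background
#'
#' The buffer width equals the maximum of the occurrence extent in the
#' latitudinal and longitudinal directions (the longitudinal extent
#' measured in km at the mean latitude), clamped to a minimum of
#' 1000 km and a maximum of 3000 km so backgrounds stay within the area
#' plausibly available to a species in its recent biogeographic
#' history.
#'
#' @param occs an [OccurrenceSet-class] with at least one record.
#' @param minKm,maxKm clamp bounds in km (defaults 1000 and 3000).
#' @return buffer width in km.
#' @examples
#' occs <- OccurrenceSet("sp", c(0, 1), c(0, 1), c(50, 50))
#' computeBuffer(occs) # small extent, clamped to 1000 km
#' @export
computeBuffer <- function(occs, minKm = 1000, maxKm = 3000) {
  if (length(occs) == 0) stop("occurrence set is empty", call. = FALSE)
  latKm <- (max(occs@lat) - min(occs@lat)) * KM_PER_DEG
  meanLat <- mean(occs@lat)
  lonKm <- (max(occs@lon) - min(occs@lon)) * KM_PER_DEG *
    cos(meanLat * pi / 180)
  min(max(max(latKm, lonKm), minKm), maxKm)
}

#' Target-group background for a modelling unit
#'
#' The background is the set of unique lattice cells of the target-group
#' pool (all occurrence records of the broader taxon, which carry the
#' same sampling bias as the presences) falling inside the modelling
#' unit's occurrence bounding box expanded by the buffer width. The
#' unit's own presence cells are part of the pool.
#'
#' @param pool [OccurrenceSet-class] of all target-group records
#'   (including the unit's own).
#' @param muOccs [OccurrenceSet-class] of the modelling unit.
#' @param widthKm buffer width in km (see [computeBuffer()]).
#' @param spec the [GridSpec-class] lattice.
#' @return list with `cells` (data.frame row/col/lon/lat of background
#'   cells), `extent` (named vector west/east/south/north of the
#'   buffered box, degrees), `widthKm` and `poolSize`.
#' @export
buildBackground <- function(pool, muOccs, widthKm, spec) {
  if (length(pool) == 0) stop("background pool is empty", call. = FALSE)
  if (length(muOccs) == 0) stop("modelling unit has no occurrences", call. = FALSE)
  meanLat <- mean(muOccs@lat)
  dLat <- widthKm / KM_PER_DEG
  dLon <- widthKm / (KM_PER_DEG * max(cos(meanLat * pi / 180), 1e-6))
  ext <- c(
    west = min(muOccs@lon) - dLon, east = max(muOccs@lon) + dLon,
    south = min(muOccs@lat) - dLat, north = max(muOccs@lat) + dLat
  )
  inBox <- pool@lon >= ext["west"] & pool@lon <= ext["east"] &
    pool@lat >= ext["south"] & pool@lat <= ext["north"]
  rc <- cellOf(spec, pool@lon[inBox], pool@lat[inBox])
  rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
  if (nrow(rc) == 0)
    stop("no pool record falls inside the buffered extent", call. = FALSE)
  rc <- unique(rc)
  rc <- rc[order(rc[, 1], rc[, 2]), , drop = FALSE]
  xy <- coordOf(spec, rc[, 1], rc[, 2])
  list(
    cells = data.frame(
      row = rc[, 1], col = rc[, 2], lon = xy[, 1], lat = xy[, 2]
    ),
    extent = ext, widthKm = widthKm, poolSize = length(pool)
  )
}
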