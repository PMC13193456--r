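#' GridSpec: a fixed WGS84 raster lattice
#'
#' Describes an axis-aligned lattice of square cells in geographic
#' coordinates (WGS84). `originLon`/`originLat` give the north-west
#' corner of cell (1,1); rows run southwards, columns eastwards. The
#' default cell size of 0.01 decimal degrees (~1.1 km at the equator) is
#' the working resolution of the whole pipeline.
#'
#' @slot originLon longitude of the western edge of the grid (degrees).
#' @slot originLat latitude of the northern edge of the grid (degrees).
#' @slot nRows,nCols lattice dimensions.
#' @slot cellSize cell edge length in decimal degrees.
#' @slot nodata sentinel value used when writing rasters to disk;
#'   in memory nodata cells are `NA`.
#' @export
setClass("GridSpec",
  representation(
    originLon = "numeric", originLat = "numeric",
    nRows = "integer", nCols = "integer",
    cellSize = "numeric", nodata = "numeric"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1 || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  if (!is.finite(object@originLon) || !is.finite(object@originLat))
    msg <- c(msg, "origin coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param originLon,originLat north-west corner of the lattice (degrees).
#' @param nRows,nCols lattice dimensions.
#' @param cellSize cell edge length in decimal degrees (default 0.01).
#' @param nodata sentinel written to file for missing cells.
#' @return a [GridSpec-class] object.
#' @examples
#' spec <- GridSpec(0, 10, nRows = 50, nCols = 80)
#' cellSize(spec)
#' @export
GridSpec <- function(originLon, originLat, nRows, nCols,
                     cellSize = 0.01, nodata = -9999) {
  new("GridSpec",
    originLon = as.numeric(originLon), originLat = as.numeric(originLat),
    nRows = as.integer(nRows), nCols = as.integer(nCols),
    cellSize = as.numeric(cellSize), nodata = as.numeric(nodata)
  )
}

#' GeoGrid: a raster of cell values on a GridSpec lattice
#'
#' The workhorse container of the pipeline; carries habitat suitability,
#' human population density, accumulated cost distance and overlap-index
#' surfaces. Nodata cells are `NA` and never enter arithmetic.
#'
#' @slot spec the [GridSpec-class] lattice.
#' @slot values numeric matrix, `nRows x nCols`, row 1 = northernmost.
#' @export
setClass("GeoGrid",
  representation(spec = "GridSpec", values = "matrix")
)

setValidity("GeoGrid", function(object) {
  d <- dim(object@values)
  if (d[1] != object@spec@nRows || d[2] != object@spec@nCols)
    return(sprintf(
      "values matrix is %d x %d but spec says %d x %d",
      d[1], d[2], object@spec@nRows, object@spec@nCols
    ))
  TRUE
})

#' Construct a GeoGrid
#'
#' @param spec a [GridSpec-class].
#' @param values numeric matrix (`nRows x nCols`, row 1 northernmost) or a
#'   single number recycled to all cells.
#' @return a [GeoGrid-class].
#' @examples
#' g <- GeoGrid(GridSpec(0, 1, 10, 10), 0.5)
#' range(gridValues(g))
#' @export
GeoGrid <- function(spec, values) {
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), spec@nRows, spec@nCols)
  storage.mode(values) <- "double"
  new("GeoGrid", spec = spec, values = values)
}

#' OccurrenceSet: species occurrence records
#'
#' Point records of where a species (or modelling unit) was observed,
#' each with a positional uncertainty in meters. After snapping to a
#' lattice (see [readOccurrences()]) a set holds at most one record per
#' grid cell.
#'
#' @slot species character species/MU identifier(s).
#' @slot lon,lat record coordinates in degrees.
#' @slot uncertainty positional uncertainty in meters.
#' @export
setClass("OccurrenceSet",
  representation(
    species = "character", lon = "numeric",
    lat = "numeric", uncertainty = "numeric"
  )
)

setValidity("OccurrenceSet", function(object) {
  n <- length(object@lon)
  msg <- character()
  if (length(object@lat) != n || length(object@uncertainty) != n ||
    length(object@species) != n)
    msg <- c(msg, "species, lon, lat, uncertainty must have equal length")
  if (n && (any(object@lon < -180 | object@lon > 180) ||
    any(object@lat < -90 | object@lat > 90)))
    msg <- c(msg, "coordinates outside valid lon/lat ranges")
  if (length(msg)) msg else TRUE
})

#' Construct an OccurrenceSet
#'
#' @param species character vector (recycled if length 1).
#' @param lon,lat coordinates in degrees.
#' @param uncertainty positional uncertainty in meters.
#' @return an [OccurrenceSet-class].
#' @export
OccurrenceSet <- function(species = character(), lon = numeric(),
                          lat = numeric(), uncertainty = numeric()) {
  n <- length(lon)
  if (length(species) == 1L && n > 1L) species <- rep(species, n)
  if (length(uncertainty) == 1L && n > 1L) uncertainty <- rep(uncertainty, n)
  new("OccurrenceSet",
    species = as.character(species), lon = as.numeric(lon),
    lat = as.numeric(lat), uncertainty = as.numeric(uncertainty)
  )
}

#' NicheModel: a fitted Maxent-style penalized Gibbs model
#'
#' Holds the sparse feature weights of an L1-penalized Gibbs
#' distribution over background-plus-presence cells, together with
#' everything needed to project it: feature definitions (knots,
#' standardization constants), per-variable training ranges used for
#' clamping, the log normalizer and entropy of the fitted density (for
#' the logistic output), the balance threshold, cross-validation AUCs
#' and permutation importances.
#'
#' @slot features a `FeatureDef` list as built by [buildFeatures()].
#' @slot weights numeric feature weights.
#' @slot logZ log normalizer of the Gibbs density over the training set.
#' @slot entropy entropy of the fitted density (nats).
#' @slot lambda per-feature L1 penalties used in fitting.
#' @slot trainRange 2 x p matrix of per-variable training min/max.
#' @slot threshold balance threshold on the logistic output (NA until
#'   computed).
#' @slot cvAUC numeric vector of test AUCs from cross-validation.
#' @slot importance named permutation importances summing to 100.
#' @slot converged logical; `iterations` actually used.
#' @slot iterations integer iteration count of the optimizer.
#' @export
setClass("NicheModel",
  representation(
    features = "list", weights = "numeric", logZ = "numeric",
    entropy = "numeric", lambda = "numeric", trainRange = "matrix",
    threshold = "numeric", cvAUC = "numeric", importance = "numeric",
    converged = "logical", iterations = "integer"
  )
)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d cells of %g deg, NW corner (%g, %g), nodata %g\n",
    object@nRows, object@nCols, object@cellSize,
    object@originLon, object@originLat, object@nodata
  ))
})

setMethod("show", "GeoGrid", function(object) {
  v <- object@values
  ok <- !is.na(v)
  cat(sprintf(
    "GeoGrid: %d x %d cells (%g deg), %d nodata\n",
    nrow(v), ncol(v), object@spec@cellSize, sum(!ok)
  ))
  if (any(ok)) {
    cat(sprintf(
      "  values: min %.4g, median %.4g, max %.4g\n",
      min(v[ok]), stats::median(v[ok]), max(v[ok])
    ))
  }
})

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf(
    "OccurrenceSet: %d records, %d species\n",
    length(object@lon), length(unique(object@species))
  ))
})

setMethod("show", "NicheModel", function(object) {
  nz <- sum(object@weights != 0)
  cat(sprintf(
    "NicheModel: %d variables, %d/%d nonzero feature weights\n",
    ncol(object@trainRange), nz, length(object@weights)
  ))
  if (length(object@cvAUC))
    cat(sprintf("  mean CV test AUC: %.3f\n", mean(object@cvAUC)))
  if (!is.na(object@threshold))
    cat(sprintf("  balance threshold: %.4f\n", object@threshold))
})

setMethod("gridSpec", "GeoGrid", function(x) x@spec)
setMethod("gridValues", "GeoGrid", function(x) x@values)
setMethod("gridValues<-", "GeoGrid", function(x, value) {
  x@values <- value
  validObject(x)
  x
})
setMethod("nRows", "GridSpec", function(x) x@nRows)
setMethod("nCols", "GridSpec", function(x) x@nCols)
setMethod("nRows", "GeoGrid", function(x) x@spec@nRows)
setMethod("nCols", "GeoGrid", function(x) x@spec@nCols)
setMethod("cellSize", "GridSpec", function(x) x@cellSize)
setMethod("cellSize", "GeoGrid", function(x) x@spec@cellSize)
setMethod("occRecords", "OccurrenceSet", function(x) {
  data.frame(
    species = x@species, lon = x@lon, lat = x@lat,
    uncertainty_m = x@uncertainty, stringsAsFactors = FALSE
  )
})

#' Number of records in an OccurrenceSet
#' @param x an [OccurrenceSet-class].
#' @export
setMethod("length", "OccurrenceSet", function(x) length(x@lon))
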