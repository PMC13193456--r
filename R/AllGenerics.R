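#' @title Generics for grid and occurrence containers
#' @name snakeOverlap-generics
#' @keywords internal
NULL

#' Extract the lattice specification of an object
#'
#' @param x a [GeoGrid-class] or other gridded object.
#' @return a [GridSpec-class].
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' Extract the cell-value matrix of a grid
#'
#' Values are returned as an `n_rows x n_cols` numeric matrix with `NA`
#' in nodata cells; row 1 is the northernmost row.
#'
#' @param x a [GeoGrid-class].
#' @return numeric matrix.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Replace the cell-value matrix of a grid
#'
#' @param x a [GeoGrid-class].
#' @param value numeric matrix of matching dimensions.
#' @export
setGeneric("gridValues<-", function(x, value) standardGeneric("gridValues<-"))

#' Number of rows / columns of a gridded object
#'
#' @param x a [GridSpec-class] or [GeoGrid-class].
#' @return integer count.
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @rdname nRows
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))

#' Cell size in decimal degrees
#'
#' @param x a [GridSpec-class] or [GeoGrid-class].
#' @return numeric scalar (degrees).
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' Occurrence records as a data.frame
#'
#' @param x an [OccurrenceSet-class].
#' @return `data.frame` with columns `species`, `lon`, `lat`,
#'   `uncertainty_m`.
#' @export
setGeneric("occRecords", function(x) standardGeneric("occRecords"))
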