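#' Map points to lattice cells and back
#'
#' The lattice convention is fixed: cell (1,1) is the north-west corner;
#' a point belongs to the cell whose half-open interval
#' `[west, east) x (south, north]` contains it, so points on a cell's
#' northern edge belong to that cell and points on its eastern edge to
#' the neighbour. `cellOf` and `coordOf` round-trip exactly on cell
#' centers.
#'
#' @param spec a [GridSpec-class].
#' @param lon,lat point coordinates in degrees.
#' @return `cellOf`: a 2-column integer matrix of (row, col) indices,
#'   `NA` for points outside the lattice. `coordOf`: a 2-column numeric
#'   matrix of cell-center (lon, lat).
#' @examples
#' spec <- GridSpec(0, 1, 10, 10, cellSize = 0.1)
#' cellOf(spec, 0.05, 0.95) # cell (1, 1)
#' @export
cellOf <- function(spec, lon, lat) {
  cs <- spec@cellSize
  col <- floor((lon - spec@originLon) / cs) + 1L
  # northern edge inclusive: lat == top of cell i maps to row i
  di <- (spec@originLat - lat) / cs
  row <- floor(di) + 1L
  on_edge <- abs(di - round(di)) < 1e-9 & round(di) > 0
  row[on_edge] <- round(di[on_edge])
  bad <- row < 1L | row > spec@nRows | col < 1L | col > spec@nCols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @rdname cellOf
#' @param row,col cell indices (1-based).
#' @export
coordOf <- function(spec, row, col) {
  cs <- spec@cellSize
  cbind(
    lon = spec@originLon + (col - 0.5) * cs,
    lat = spec@originLat - (row - 0.5) * cs
  )
}

#' Cell-center coordinates of every lattice cell
#'
#' @param spec a [GridSpec-class].
#' @return data.frame with `row`, `col`, `lon`, `lat` in matrix column
#'   order (column-major, matching `as.vector` on a values matrix).
#' @export
cellCenters <- function(spec) {
  idx <- expand.grid(row = seq_len(spec@nRows), col = seq_len(spec@nCols))
  xy <- coordOf(spec, idx$row, idx$col)
  data.frame(row = idx$row, col = idx$col, lon = xy[, 1], lat = xy[, 2])
}

sameLattice <- function(a, b, tol = 1e-9) {
  sa <- if (is(a, "GeoGrid")) a@spec else a
  sb <- if (is(b, "GeoGrid")) b@spec else b
  abs(sa@originLon - sb@originLon) < tol &&
    abs(sa@originLat - sb@originLat) < tol &&
    sa@nRows == sb@nRows && sa@nCols == sb@nCols &&
    abs(sa@cellSize - sb@cellSize) < tol
}

stopIfMisaligned <- function(a, b, what = "grids") {
  if (!sameLattice(a, b)) stop(what, " are not on the same lattice", call. = FALSE)
  invisible(TRUE)
}

#' Apply a function cellwise over aligned grids
#'
#' @param grids list of aligned [GeoGrid-class] objects.
#' @param f function applied to the stacked values (receives a matrix
#'   with one column per grid, one row per cell) or one of the fast
#'   paths `"sum"`, `"max"`.
#' @return a [GeoGrid-class] on the shared lattice.
#' @keywords internal
gridApply <- function(grids, f) {
  stopifnot(length(grids) >= 1)
  for (g in grids[-1]) stopIfMisaligned(grids[[1]], g)
  vals <- vapply(grids, function(g) as.vector(g@values),
    numeric(length(grids[[1]]@values))
  )
  vals <- matrix(vals, ncol = length(grids))
  out <- if (identical(f, "sum")) {
    rowSums(vals)
  } else if (identical(f, "max")) {
    do.call(pmax, c(asplit(vals, 2), list(na.rm = FALSE)))
  } else {
    apply(vals, 1, f)
  }
  GeoGrid(grids[[1]]@spec, matrix(out, nRows(grids[[1]]), nCols(grids[[1]])))
}
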