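#' Read and write rasters as ESRI ASCII grids
#'
#' Rasters are stored in the plain-text ESRI ASCII grid format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' followed by rows north to south). Values are written with 17
#' significant digits so a write/read round trip reproduces doubles
#' bit-exactly. A WKT `.prj` sidecar pins the CRS to WGS84; reading a
#' file whose sidecar names another CRS is an error.
#'
#' @param grid a [GeoGrid-class].
#' @param path file path (conventionally `.asc`).
#' @return `readAsciiGrid` returns a [GeoGrid-class]; `writeAsciiGrid`
#'   returns `path` invisibly.
#' @export
writeAsciiGrid <- function(grid, path) {
  spec <- grid@spec
  v <- grid@values
  v[is.na(v)] <- spec@nodata
  hdr <- c(
    sprintf("ncols %d", spec@nCols),
    sprintf("nrows %d", spec@nRows),
    sprintf("xllcorner %.17g", spec@originLon),
    sprintf("yllcorner %.17g", spec@originLat - spec@nRows * spec@cellSize),
    sprintf("cellsize %.17g", spec@cellSize),
    sprintf("NODATA_value %.17g", spec@nodata)
  )
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(wgs84Wkt(), prjPath(path))
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  prj <- prjPath(path)
  if (file.exists(prj)) {
    wkt <- paste(readLines(prj, warn = FALSE), collapse = " ")
    if (!grepl("WGS[ _]?(19)?84|4326", wkt, ignore.case = TRUE))
      stop("raster CRS is not WGS84: ", substr(wkt, 1, 60), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("malformed ASCII grid: ", path, call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed ASCII grid header: ", lines[i], call. = FALSE)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need])))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("malformed ASCII grid: expected ", nr * nc, " values, got ",
      length(vals), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  spec <- GridSpec(
    originLon = hdr$xllcorner,
    originLat = hdr$yllcorner + nr * hdr$cellsize,
    nRows = nr, nCols = nc, cellSize = hdr$cellsize,
    nodata = hdr$nodata_value
  )
  GeoGrid(spec, m)
}

prjPath <- function(path) sub("\\.[^.]*$", "", path) |> paste0(".prj")

wgs84Wkt <- function() {
  paste0(
    'GEOGCS["WGS 84",DATUM["WGS_1984",SPHEROID["WGS 84",6378137,',
    '298.257223563]],PRIMEM["Greenwich",0],UNIT["degree",0.0174532925199433],',
    'AUTHORITY["EPSG","4326"]]'
  )
}

#' Write and read polygon sets as GeoJSON
#'
#' A polygon set is a list of polygons; each polygon is a list of rings;
#' each ring is a 2-column (lon, lat) matrix, closed (first point
#' repeated last). Written as a GeoJSON `MultiPolygon` feature.
#'
#' @param polys polygon set (possibly empty list).
#' @param path file path.
#' @param properties optional named list stored on the feature.
#' @return `readGeoJSON` returns a polygon set.
#' @export
writeGeoJSON <- function(polys, path, properties = list(id = "edr")) {
  coords <- lapply(polys, function(poly) {
    lapply(poly, function(ring) {
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    })
  })
  obj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = properties,
      geometry = list(type = "MultiPolygon", coordinates = coords)
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGeoJSON
#' @export
readGeoJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  polys <- list()
  for (feat in obj$features) {
    geom <- feat$geometry
    mp <- if (identical(geom$type, "Polygon")) list(geom$coordinates) else geom$coordinates
    for (poly in mp) {
      rings <- lapply(poly, function(ring) {
        do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      })
      polys[[length(polys) + 1L]] <- rings
    }
  }
  polys
}

#' Rasterize polygons by cell-center containment
#'
#' A cell is inside if its center falls inside an odd number of ring
#' crossings (even-odd rule), so holes are supported.
#'
#' @param polys polygon set as in [writeGeoJSON()].
#' @param spec target [GridSpec-class].
#' @return a [GeoGrid-class] of 0/1 values.
#' @export
rasterizePolygons <- function(polys, spec) {
  cc <- cellCenters(spec)
  inside <- rep(0L, nrow(cc))
  for (poly in polys) {
    for (ring in poly) {
      inside <- inside + ringCrossings(ring, cc$lon, cc$lat)
    }
  }
  GeoGrid(spec, matrix(as.numeric(inside %% 2L), spec@nRows, spec@nCols))
}

# number of times a horizontal ray from each point crosses the ring
ringCrossings <- function(ring, px, py) {
  n <- nrow(ring)
  cross <- integer(length(px))
  for (k in seq_len(n - 1)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
    hit <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    cross <- cross + as.integer(hit)
  }
  cross
}

#' Read occurrence records and snap them to the lattice
#'
#' Reads a CSV with columns `species`, `lon`, `lat`, `uncertainty_m`,
#' drops records outside the lattice, snaps coordinates to cell centers
#' and keeps at most one record per species per cell — the record with
#' the smallest positional uncertainty (ties broken by file order).
#'
#' @param path CSV file path.
#' @param spec the target [GridSpec-class].
#' @return an [OccurrenceSet-class].
#' @export
readOccurrences <- function(path, spec) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat", "uncertainty_m")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("occurrence file missing column(s): ",
      paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) {
    warning("occurrence file is empty: ", path)
    return(OccurrenceSet())
  }
  occs <- OccurrenceSet(df$species, df$lon, df$lat, df$uncertainty_m)
  snapOccurrences(occs, spec)
}

#' Snap occurrences to cell centers and deduplicate per cell
#'
#' @param occs an [OccurrenceSet-class].
#' @param spec a [GridSpec-class].
#' @return an [OccurrenceSet-class] with one record per species per cell.
#' @export
snapOccurrences <- function(occs, spec) {
  if (length(occs) == 0) return(occs)
  rc <- cellOf(spec, occs@lon, occs@lat)
  keep <- !is.na(rc[, 1])
  rc <- rc[keep, , drop = FALSE]
  sp <- occs@species[keep]
  unc <- occs@uncertainty[keep]
  if (!length(sp)) return(OccurrenceSet())
  key <- paste(sp, rc[, 1], rc[, 2], sep = "\r")
  # stable order by uncertainty: first record wins ties
  o <- order(unc)
  first <- o[!duplicated(key[o])]
  first <- sort(first)
  xy <- coordOf(spec, rc[first, 1], rc[first, 2])
  OccurrenceSet(sp[first], xy[, 1], xy[, 2], unc[first])
}

#' Keep the most accurately located 75\% of records per species
#'
#' Records are ranked by positional uncertainty and only the 75\% with
#' the smallest uncertainty retained (`floor(0.75 n)` when fractional).
#' Species with fewer than 20 records are exempt and keep all records,
#' since model accuracy degrades fastest below that count.
#'
#' @param occs an [OccurrenceSet-class].
#' @param frac fraction retained (default 0.75).
#' @param minRecords exemption cutoff (default 20).
#' @return a filtered [OccurrenceSet-class].
#' @export
filterByAccuracy <- function(occs, frac = 0.75, minRecords = 20) {
  if (length(occs) == 0) return(occs)
  keep <- logical(length(occs))
  for (sp in unique(occs@species)) {
    idx <- which(occs@species == sp)
    n <- length(idx)
    if (n < minRecords) {
      keep[idx] <- TRUE
    } else {
      k <- floor(frac * n)
      o <- order(occs@uncertainty[idx]) # stable: ties by record order
      keep[idx[o[seq_len(k)]]] <- TRUE
    }
  }
  OccurrenceSet(
    occs@species[keep], occs@lon[keep], occs@lat[keep],
    occs@uncertainty[keep]
  )
}

#' Align a raster to a target lattice
#'
#' Finer inputs are aggregated blockwise (`mode = "mean"` for continuous
#' layers, `mode = "mode"` for categorical, ties to the smallest value);
#' coarser inputs are resampled by nearest neighbour. Input and target
#' resolutions must be integer multiples of one another and share an
#' origin.
#'
#' @param raster input [GeoGrid-class].
#' @param spec target [GridSpec-class].
#' @param mode `"mean"`, `"mode"` or `"nearest"` (nearest is implied
#'   whenever the input is coarser than the target).
#' @return a [GeoGrid-class] on `spec`.
#' @export
alignToGrid <- function(raster, spec, mode = c("mean", "mode", "nearest")) {
  mode <- match.arg(mode)
  inSpec <- raster@spec
  tol <- 1e-9
  if (abs(inSpec@originLon - spec@originLon) > tol ||
    abs(inSpec@originLat - spec@originLat) > tol)
    stop("raster origin does not match target lattice", call. = FALSE)
  ratio <- spec@cellSize / inSpec@cellSize
  if (abs(ratio - 1) < tol) {
    if (inSpec@nRows != spec@nRows || inSpec@nCols != spec@nCols)
      stop("same resolution but different extent", call. = FALSE)
    return(GeoGrid(spec, raster@values))
  }
  if (ratio > 1) { # input finer: aggregate
    f <- round(ratio)
    if (abs(ratio - f) > 1e-6)
      stop("non-commensurate resolutions: ", inSpec@cellSize, " vs ",
        spec@cellSize, call. = FALSE)
    if (inSpec@nRows != spec@nRows * f || inSpec@nCols != spec@nCols * f)
      stop("input extent does not tile the target lattice", call. = FALSE)
    agg <- if (mode == "mode") blockMode else blockMean
    return(GeoGrid(spec, agg(raster@values, f)))
  }
  inv <- 1 / ratio # input coarser: nearest-neighbour resample
  f <- round(inv)
  if (abs(inv - f) > 1e-6)
    stop("non-commensurate resolutions: ", inSpec@cellSize, " vs ",
      spec@cellSize, call. = FALSE)
  if (spec@nRows != inSpec@nRows * f || spec@nCols != inSpec@nCols * f)
    stop("target extent does not tile the input lattice", call. = FALSE)
  ri <- ceiling(seq_len(spec@nRows) / f)
  ci <- ceiling(seq_len(spec@nCols) / f)
  GeoGrid(spec, raster@values[ri, ci, drop = FALSE])
}

blockMean <- function(m, f) {
  nr <- nrow(m) / f
  nc <- ncol(m) / f
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1) * f + 1):(i * f)
    for (j in seq_len(nc)) {
      blk <- m[rows, ((j - 1) * f + 1):(j * f)]
      if (any(!is.na(blk))) out[i, j] <- mean(blk, na.rm = TRUE)
    }
  }
  out
}

blockMode <- function(m, f) {
  nr <- nrow(m) / f
  nc <- ncol(m) / f
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1) * f + 1):(i * f)
    for (j in seq_len(nc)) {
      blk <- m[rows, ((j - 1) * f + 1):(j * f)]
      blk <- blk[!is.na(blk)]
      if (length(blk)) {
        tab <- table(blk)
        best <- names(tab)[tab == max(tab)]
        out[i, j] <- min(as.numeric(best)) # tie: smallest value
      }
    }
  }
  out
}
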