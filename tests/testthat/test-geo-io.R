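test_that("ASCII grid write/read round-trips values, nodata and geometry", {
  spec <- GridSpec(12.34, -5.67, 9, 7, cellSize = 0.01, nodata = -99)
  set.seed(1)
  v <- matrix(rnorm(63), 9, 7)
  v[2, 3] <- NA
  v[9, 1] <- NA
  g <- GeoGrid(spec, v)
  path <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(g, path)
  back <- readAsciiGrid(path)
  expect_identical(gridValues(back), v)
  expect_identical(cellSize(back), 0.01)
  expect_identical(gridSpec(back)@originLon, 12.34)
  expect_identical(gridSpec(back)@originLat, -5.67)
  expect_identical(gridSpec(back)@nodata, -99)
})

test_that("reading rejects non-WGS84 sidecars and malformed files", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(gridOf(1, 2, 2), path)
  writeLines('PROJCS["NAD83 / UTM zone 10N"]', sub("asc$", "prj", path))
  expect_error(readAsciiGrid(path), "NAD83")
  bad <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "oops"), bad)
  expect_error(readAsciiGrid(bad), "malformed")
  expect_error(readAsciiGrid("no/such/file.asc"), "not found")
})

test_that("GeoJSON polygons round-trip and rasterize by cell center", {
  spec <- tinySpec(6, 6)
  ring <- rbind(
    c(0.01, 0.01), c(0.04, 0.01), c(0.04, 0.05), c(0.01, 0.05), c(0.01, 0.01)
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  writeGeoJSON(list(list(ring)), path)
  back <- readGeoJSON(path)
  expect_equal(back[[1]][[1]], ring)
  mask <- rasterizePolygons(back, spec)
  # cells with centers strictly inside: cols 2-4, rows 2-5
  expect_equal(sum(gridValues(mask)), 12)
})

test_that("occurrence reading needs its columns and collapses cells", {
  spec <- tinySpec()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(species = "a", lon = 1, lat = 2), path,
    row.names = FALSE
  )
  expect_error(readOccurrences(path, spec), "uncertainty_m")

  empty <- withr::local_tempfile(fileext = ".csv")
  write.csv(
    data.frame(
      species = character(), lon = numeric(), lat = numeric(),
      uncertainty_m = numeric()
    ),
    empty, row.names = FALSE
  )
  expect_warning(o <- readOccurrences(empty, spec), "empty")
  expect_equal(length(o), 0L)

  # 12 records in 7 distinct cells -> 7 records, keeping the most
  # accurate record of each cell
  cells <- rbind(
    c(1, 1), c(1, 1), c(1, 1), c(2, 2), c(2, 2), c(3, 5), c(3, 5),
    c(4, 4), c(5, 1), c(6, 6), c(6, 6), c(9, 9)
  )
  xy <- coordOf(spec, cells[, 1], cells[, 2])
  df <- data.frame(
    species = "sp1", lon = xy[, 1], lat = xy[, 2],
    uncertainty_m = c(30, 10, 20, 5, 50, 7, 7, 1, 2, 90, 40, 3)
  )
  many <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, many, row.names = FALSE)
  o <- readOccurrences(many, spec)
  expect_equal(length(o), 7L)
  got <- occRecords(o)
  expect_setequal(got$uncertainty_m, c(10, 5, 7, 1, 2, 40, 3))
})

test_that("five records in one cell collapse to one", {
  spec <- tinySpec()
  o <- OccurrenceSet("x", rep(0.015, 5), rep(0.055, 5), c(9, 3, 5, 3, 8))
  snapped <- snapOccurrences(o, spec)
  expect_equal(length(snapped), 1L)
  expect_equal(snapped@uncertainty, 3) # smallest; tie broken by order
})

test_that("accuracy filter keeps the best 75% except for sparse species", {
  set.seed(7)
  o100 <- OccurrenceSet("a", runif(100), runif(100), sample(1000, 100))
  kept <- filterByAccuracy(o100)
  expect_equal(length(kept), 75L)
  expect_lte(max(kept@uncertainty), min(setdiff(o100@uncertainty, kept@uncertainty)))

  o18 <- OccurrenceSet("b", runif(18), runif(18), runif(18, 1, 500))
  expect_equal(length(filterByAccuracy(o18)), 18L)

  # fractional count floors: 21 records -> floor(15.75) = 15
  o21 <- OccurrenceSet("c", runif(21), runif(21), runif(21, 1, 500))
  expect_equal(length(filterByAccuracy(o21)), 15L)

  # filtering is per species: each treated on its own count
  both <- OccurrenceSet(
    c(o100@species, o18@species), c(o100@lon, o18@lon),
    c(o100@lat, o18@lat), c(o100@uncertainty, o18@uncertainty)
  )
  keptBoth <- filterByAccuracy(both)
  expect_equal(sum(keptBoth@species == "a"), 75L)
  expect_equal(sum(keptBoth@species == "b"), 18L)
})

test_that("alignToGrid aggregates finer rasters and resamples coarser ones", {
  fine <- GridSpec(0, 0.1, 10, 10, cellSize = 0.01)
  coarse <- GridSpec(0, 0.1, 5, 5, cellSize = 0.02)
  set.seed(2)
  v <- matrix(rnorm(100), 10, 10)
  g <- GeoGrid(fine, v)
  agg <- alignToGrid(g, coarse, "mean")
  # loop oracle: each output cell is the mean of its 2x2 block
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(
        gridValues(agg)[i, j],
        mean(v[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
      )
    }
  }
  # identity at equal resolution
  expect_identical(gridValues(alignToGrid(g, fine)), v)
  # categorical aggregation yields only observed categories
  cats <- GeoGrid(fine, matrix(sample(1:4, 100, TRUE), 10, 10))
  aggc <- alignToGrid(cats, coarse, "mode")
  expect_true(all(gridValues(aggc) %in% 1:4))
  # nearest-neighbour upsampling replicates the coarse blocks
  up <- alignToGrid(aggc, fine)
  expect_identical(gridValues(up)[1:2, 1:2], matrix(gridValues(aggc)[1, 1], 2, 2))
  # non-commensurate resolutions are refused
  odd <- GridSpec(0, 0.1, 3, 3, cellSize = 0.1 / 3)
  expect_error(alignToGrid(g, odd), "non-commensurate")
})
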