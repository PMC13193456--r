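test_that("GCM summaries are cellwise quantiles in the right order", {
  spec <- tinySpec(5, 5)
  set.seed(4)
  grids <- lapply(1:7, function(i) GeoGrid(spec, matrix(runif(25), 5, 5)))
  gs <- summarizeGcms(grids)
  expect_equal(gs$nGcms, 7)
  vals <- vapply(grids, function(g) as.vector(gridValues(g)), numeric(25))
  for (cell in 1:25) {
    expect_equal(
      as.vector(gridValues(gs$median))[cell],
      quantile(vals[cell, ], 0.5, names = FALSE)
    )
    expect_equal(
      as.vector(gridValues(gs$q10))[cell],
      quantile(vals[cell, ], 0.1, names = FALSE)
    )
  }
  expect_true(all(gridValues(gs$q10) <= gridValues(gs$median)))
  expect_true(all(gridValues(gs$median) <= gridValues(gs$q90)))
  # identical inputs collapse to the input
  same <- summarizeGcms(list(grids[[1]], grids[[1]], grids[[1]]))
  expect_equal(gridValues(same$q10), gridValues(grids[[1]]))
  expect_equal(gridValues(same$q90), gridValues(grids[[1]]))
  expect_error(summarizeGcms(list(grids[[1]])), "at least 2")
})

test_that("change metrics satisfy the expansion/contraction identity", {
  spec <- tinySpec(2, 5)
  cur <- GeoGrid(spec, matrix(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 2, 5))
  # 3 gained, 2 lost
  fut <- GeoGrid(spec, matrix(c(1, 1, 1, 0, 0, 1, 1, 1, 0, 0), 2, 5))
  cm <- changeMetrics(cur, fut)
  expect_equal(cm$expansion, 3)
  expect_equal(cm$contraction, 2)
  expect_equal(cm$rangeFuture, cm$rangeCurrent + cm$expansion - cm$contraction)

  same <- changeMetrics(cur, cur)
  expect_equal(same$expansion, 0)
  expect_equal(same$contraction, 0)

  gone <- changeMetrics(cur, GeoGrid(spec, 0))
  expect_equal(gone$totalSuitFuture, 0)
  expect_equal(gone$contraction, gone$rangeCurrent)

  # identity on random instances
  set.seed(11)
  for (i in 1:20) {
    a <- GeoGrid(spec, matrix(rbinom(10, 1, 0.5) * runif(10), 2, 5))
    b <- GeoGrid(spec, matrix(rbinom(10, 1, 0.5) * runif(10), 2, 5))
    m <- changeMetrics(a, b)
    expect_equal(m$rangeFuture, m$rangeCurrent + m$expansion - m$contraction)
  }
})

test_that("range centroids are coordinate means of suitable cells", {
  spec <- GridSpec(0, 1, 10, 10, cellSize = 0.2) # spans the equator
  v <- matrix(0, 10, 10)
  v[3, 4] <- 1
  g <- GeoGrid(spec, v)
  expect_equal(rangeCentroid(g), c(lon = 0.7, lat = 0.5))
  # symmetric pair about the equator
  v2 <- matrix(0, 10, 10)
  v2[2, 5] <- 1 # lat 0.7
  v2[9, 5] <- 1 # lat -0.7
  expect_equal(rangeCentroid(GeoGrid(spec, v2))[["lat"]], 0)
  # loop oracle on a random mask
  set.seed(13)
  v3 <- matrix(rbinom(100, 1, 0.3) * runif(100), 10, 10)
  cc <- cellCenters(spec)
  on <- as.vector(v3) > 0
  expect_equal(
    rangeCentroid(GeoGrid(spec, v3)),
    c(lon = mean(cc$lon[on]), lat = mean(cc$lat[on]))
  )
  expect_error(rangeCentroid(GeoGrid(spec, 0)), "centroid undefined")
})

test_that("shift vectors agree with an independent great-circle oracle", {
  expect_equal(shiftVector(c(lon = 5, lat = 5), c(lon = 5, lat = 5))[["D1_m"]], 0)
  # one degree east on the equator
  east <- shiftVector(c(lon = 0, lat = 0), c(lon = 1, lat = 0))
  expect_equal(east[["D1_m"]], 111194.93, tolerance = 1e-6)
  expect_equal(east[["D2_deg"]], 90)
  # one degree north: same distance, bearing 0
  north <- shiftVector(c(lon = 0, lat = 0), c(lon = 0, lat = 1))
  expect_equal(north[["D1_m"]], east[["D1_m"]])
  expect_equal(north[["D2_deg"]], 0)
  # 1000 random pairs against the independent oracle
  set.seed(17)
  lon1 <- runif(1000, -180, 180)
  lat1 <- runif(1000, -85, 85)
  lon2 <- runif(1000, -180, 180)
  lat2 <- runif(1000, -85, 85)
  for (i in seq_len(1000)) {
    got <- shiftVector(
      c(lon = lon1[i], lat = lat1[i]),
      c(lon = lon2[i], lat = lat2[i])
    )
    want <- oracleGreatCircle(lon1[i], lat1[i], lon2[i], lat2[i])
    expect_equal(got[["D1_m"]], want[["dist"]], tolerance = 1e-6)
    expect_equal(got[["D2_deg"]], want[["bearing"]], tolerance = 1e-6)
  }
})

test_that("shift vectors match the geosphere reference implementation", {
  skip_if_not_installed("geosphere")
  set.seed(19)
  p1 <- cbind(runif(50, -180, 180), runif(50, -80, 80))
  p2 <- cbind(runif(50, -180, 180), runif(50, -80, 80))
  for (i in 1:50) {
    got <- shiftVector(
      c(lon = p1[i, 1], lat = p1[i, 2]),
      c(lon = p2[i, 1], lat = p2[i, 2])
    )
    expect_equal(
      got[["D1_m"]],
      geosphere::distHaversine(p1[i, ], p2[i, ], r = 6371000),
      tolerance = 1e-9
    )
    expect_equal(
      got[["D2_deg"]],
      geosphere::bearing(p1[i, ], p2[i, ], a = 6371000, f = 0),
      tolerance = 1e-6
    )
  }
})

test_that("circular medians handle wraparound and regional summaries aggregate", {
  expect_equal(circularMedian(c(45, 45, 45)), 45)
  expect_equal(circularMedian(c(350, 10)), 0)
  expect_equal(circularMedian(c(-170, 170)), 180)
  expect_equal(circularMedian(c(10, 20, 30)), 20)
  vecs <- data.frame(
    D1_m = c(1000, 2000, 3000, 500),
    D2_deg = c(350, 10, 0, 90)
  )
  out <- regionalShiftSummary(vecs, c("A", "A", "A", "B"))
  expect_equal(nrow(out), 2)
  expect_equal(out$D2_deg[out$region == "A"], 0)
  expect_equal(out$D1_m[out$region == "A"], 2000)
  expect_equal(out$D2_deg[out$region == "B"], 90)
})
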