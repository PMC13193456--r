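# shared fixtures and independent oracles; everything is generated in
# code, nothing read from disk

tinySpec <- function(nr = 10, nc = 10, cs = 0.01) {
  GridSpec(0, nr * cs, nRows = nr, nCols = nc, cellSize = cs)
}

gridOf <- function(values, nr, nc, cs = 0.01) {
  GeoGrid(tinySpec(nr, nc, cs), matrix(values, nr, nc))
}

# small synthetic world reused across test files (built once per session)
.worldCache <- new.env(parent = emptyenv())
smallWorld <- function(nr = 60, nOcc = 150, seed = 42) {
  key <- paste(nr, nOcc, seed)
  if (!is.null(.worldCache[[key]])) return(.worldCache[[key]])
  spec <- tinySpec(nr, nr)
  stack <- genEnvStack(spec, 3, corrPairs = list(c(1, 2)), seed = seed)
  truth <- genTrueSuitability(
    stack, TruthModel(c(2.5, 0, -1.5), c(0, 0, -1), -0.5)
  )
  bias <- genBiasField(spec)
  occs <- snapOccurrences(
    genOccurrences(truth, nOcc, bias, seed = seed + 1), spec
  )
  pool <- snapOccurrences(
    genOccurrences(GeoGrid(spec, 1), 8 * nOcc, bias,
      seed = seed + 2, species = "pool"
    ), spec
  )
  envAt <- function(cells) {
    X <- vapply(stack, function(g) g@values[as.matrix(cells)],
      numeric(nrow(cells))
    )
    matrix(X, ncol = length(stack), dimnames = list(NULL, names(stack)))
  }
  presCells <- cellOf(spec, occs@lon, occs@lat)
  poolCells <- unique(rbind(presCells, cellOf(spec, pool@lon, pool@lat)))
  w <- list(
    spec = spec, stack = stack, truth = truth, bias = bias,
    occs = occs, pool = pool,
    presX = envAt(presCells), bgX = envAt(poolCells)
  )
  .worldCache[[key]] <- w
  w
}

# O(V^2) multi-source Dijkstra, independent of the igraph implementation
bruteCostDistance <- function(suitMat, srcCells, floor = 1e-6) {
  nr <- nrow(suitMat)
  nc <- ncol(suitMat)
  n <- nr * nc
  res <- 1 / pmax(as.vector(suitMat), floor)
  ok <- !is.na(as.vector(suitMat))
  dist <- rep(Inf, n)
  dist[srcCells] <- 0
  dist[!ok] <- NA
  visited <- rep(FALSE, n)
  offs <- rbind(
    c(0, 1, 1), c(0, -1, 1), c(1, 0, 1), c(-1, 0, 1),
    c(1, 1, sqrt(2)), c(1, -1, sqrt(2)), c(-1, 1, sqrt(2)),
    c(-1, -1, sqrt(2))
  )
  repeat {
    cand <- which(!visited & ok & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    visited[u] <- TRUE
    ur <- (u - 1) %% nr + 1
    uc <- (u - 1) %/% nr + 1
    for (k in seq_len(nrow(offs))) {
      vr <- ur + offs[k, 1]
      vc <- uc + offs[k, 2]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      v <- (vc - 1) * nr + vr
      if (!ok[v] || visited[v]) next
      w <- offs[k, 3] * (res[u] + res[v]) / 2
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  matrix(dist, nr, nc)
}

# independent great-circle distance/bearing (spherical law of cosines
# for the distance, so the code path differs from the haversine)
oracleGreatCircle <- function(lon1, lat1, lon2, lat2, R = 6371000) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  central <- acos(pmin(1, pmax(-1,
    sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  )))
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  c(dist = R * central, bearing = atan2(y, x) * 180 / pi)
}

# a deliberately small pipeline configuration keeps end-to-end runs quick
smallConfig <- function(outDir, seed = 1) {
  cfg <- pipelineConfig(outDir = outDir, seed = seed)
  cfg$grid$nRows <- 50
  cfg$grid$nCols <- 50
  cfg$simulate$nOccPerSpecies <- 60
  cfg$simulate$nPoolRecords <- 800
  cfg$simulate$nGcms <- 3
  cfg$simulate$futureSteps <- list(step2050 = c(env1 = 0.5, env3 = 0.4))
  cfg$thresholds$cvK <- 3
  cfg
}

occAt <- function(spec, rows, cols, species = "sp", unc = 50) {
  xy <- coordOf(spec, rows, cols)
  OccurrenceSet(species, xy[, 1], xy[, 2], rep(unc, length(rows)))
}
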