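#' Accumulated cost distance from occurrences over a suitability surface
#'
#' Multi-source shortest-path distance on the 8-connected cell lattice.
#' Each cell's resistance is the reciprocal of its habitat suitability
#' (floored to avoid division by zero); the cost of a step between
#' neighbouring cells is the step length (1 for rook moves, sqrt(2) for
#' diagonal moves) times the mean of the two cells' resistances. One
#' cost distance unit (CDU) therefore equals one rook step through
#' perfect habitat, and the accumulated cost measures how much
#' resistance must be overcome to reach a cell from the nearest known
#' occurrence. Occurrence cells have cost 0; nodata cells are
#' impassable; cells unreachable from any occurrence get `Inf`.
#'
#' @param suit suitability [GeoGrid-class] with values in \\[0, 1\\].
#' @param occs an [OccurrenceSet-class] (at least one record on a data
#'   cell).
#' @param floor minimum suitability used in the resistance (default
#'   1e-6).
#' @return a [GeoGrid-class] of accumulated cost distance.
#' @export
costDistance <- function(suit, occs, floor = 1e-6) {
  spec <- suit@spec
  nr <- spec@nRows
  nc <- spec@nCols
  v <- as.vector(suit@values)
  ok <- !is.na(v)
  res <- 1 / pmax(v, floor)
  rc <- cellOf(spec, occs@lon, occs@lat)
  rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
  src <- unique((rc[, 2] - 1L) * nr + rc[, 1])
  src <- src[ok[src]]
  if (!length(src))
    stop("no occurrence falls on a data cell of the grid", call. = FALSE)

  edges <- latticeEdges(nr, nc, ok, res)
  nCell <- nr * nc
  super <- nCell + 1L
  g <- igraph::make_empty_graph(n = super, directed = FALSE)
  g <- igraph::add_edges(g,
    rbind(c(edges$from, rep(super, length(src))), c(edges$to, src)),
    weight = c(edges$w, rep(0, length(src)))
  )
  d <- igraph::distances(g, v = super, weights = igraph::E(g)$weight)[1, ]
  out <- d[seq_len(nCell)]
  out[!ok] <- NA_real_
  GeoGrid(spec, matrix(out, nr, nc))
}

# undirected 8-neighbour edges among data cells, column-major indexing
latticeEdges <- function(nr, nc, ok, res) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  from <- integer()
  to <- integer()
  w <- numeric()
  offs <- list(
    c(0L, 1L, 1), c(1L, 0L, 1),
    c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2))
  )
  for (off in offs) {
    dr <- off[1]; dc <- off[2]; len <- off[3]
    rLo <- max(1L, 1L - dr); rHi <- min(nr, nr - dr)
    cLo <- max(1L, 1L - dc); cHi <- min(nc, nc - dc)
    if (rHi < rLo || cHi < cLo) next
    rFrom <- rLo:rHi
    cFrom <- cLo:cHi
    a <- as.vector(idx[rFrom, cFrom, drop = FALSE])
    b <- as.vector(idx[rFrom + dr, cFrom + dc, drop = FALSE])
    use <- ok[a] & ok[b]
    a <- a[use]
    b <- b[use]
    from <- c(from, a)
    to <- c(to, b)
    w <- c(w, len * (res[a] + res[b]) / 2)
  }
  list(from = from, to = to, w = w)
}

#' Clip a suitability grid by maximum cost distance
#'
#' Cells farther than `maxCdu` cost distance units from any known
#' occurrence are set to zero, removing disconnected suitable areas
#' (e.g. across dispersal barriers) and marginal habitat far from known
#' records. The unclipped surface is returned alongside, since both
#' versions are useful (the raw surface flags potentially suitable but
#' unconfirmed habitat).
#'
#' @param suit suitability [GeoGrid-class].
#' @param cost cost-distance [GeoGrid-class] from [costDistance()].
#' @param maxCdu cut-off in cost distance units (default 500); cells at
#'   exactly `maxCdu` are kept.
#' @return list with `clipped` and `raw` [GeoGrid-class] surfaces.
#' @export
clipByCdu <- function(suit, cost, maxCdu = 500) {
  stopIfMisaligned(suit, cost)
  v <- suit@values
  cd <- cost@values
  drop <- !is.na(v) & (is.na(cd) | cd > maxCdu)
  v[drop] <- 0
  list(clipped = GeoGrid(suit@spec, v), raw = suit)
}

#' Split a multi-species modelling unit with the overlap fade-out rule
#'
#' Each cell is assigned to the member species with the lowest cost
#' distance there. Within an overlap allowance (default 500 CDU) the two
#' species of lowest cost distance share the cell, with weights
#' proportional to the opposite species' cost distance:
#' `w_s = cd_other / (cd_s + cd_other)`, so two species both at 250 CDU
#' are each downweighted by 50\%, and a species is downweighted more the
#' closer its competitor is. When no second species lies within the
#' allowance the minimum-cost species keeps weight 1; any third or
#' further species within the allowance is excluded. The downweighted
#' surfaces are re-thresholded with the unit's original balance
#' threshold, removing cells of low residual suitability near another
#' member species.
#'
#' @param muSuit the modelling unit's (thresholded, rescaled)
#'   suitability [GeoGrid-class].
#' @param costs named list of per-species cost-distance
#'   [GeoGrid-class] surfaces.
#' @param overlapCdu overlap allowance in CDU (default 500).
#' @param threshold the unit's original balance threshold (applied to
#'   the downweighted values; 0 disables re-thresholding).
#' @return named list of per-species suitability [GeoGrid-class].
#' @export
splitMu <- function(muSuit, costs, overlapCdu = 500, threshold = 0) {
  nSp <- length(costs)
  stopifnot(nSp >= 1)
  if (is.null(names(costs))) names(costs) <- paste0("sp", seq_len(nSp))
  for (cg in costs) stopIfMisaligned(muSuit, cg, "suitability and cost grids")
  if (nSp == 1) {
    return(stats::setNames(list(muSuit), names(costs)))
  }
  nCell <- length(muSuit@values)
  C <- vapply(costs, function(g) as.vector(g@values), numeric(nCell))
  C <- matrix(C, nCell, nSp)
  C[is.na(C)] <- Inf

  i1 <- rep(1L, nCell)
  c1 <- C[, 1]
  for (j in 2:nSp) { # strict '<' keeps the first species on ties
    upd <- C[, j] < c1
    i1[upd] <- j
    c1[upd] <- C[upd, j]
  }
  C2 <- C
  C2[cbind(seq_len(nCell), i1)] <- Inf
  i2 <- rep(1L, nCell)
  c2 <- C2[, 1]
  for (j in 2:nSp) {
    upd <- C2[, j] < c2
    i2[upd] <- j
    c2[upd] <- C2[upd, j]
  }
  both <- c2 < overlapCdu
  tot <- c1 + c2
  w1 <- ifelse(both, ifelse(tot > 0, c2 / tot, 0.5), 1)
  w2 <- ifelse(both, ifelse(tot > 0, c1 / tot, 0.5), 0)

  W <- matrix(0, nCell, nSp)
  W[cbind(seq_len(nCell), i1)] <- w1
  W[cbind(seq_len(nCell), i2)] <- pmax(W[cbind(seq_len(nCell), i2)], w2)

  suitVec <- as.vector(muSuit@values)
  out <- lapply(seq_len(nSp), function(s) {
    v <- W[, s] * suitVec
    v[!is.na(v) & v > 0 & v < threshold] <- 0
    GeoGrid(muSuit@spec, matrix(v, muSuit@spec@nRows, muSuit@spec@nCols))
  })
  stats::setNames(out, names(costs))
}
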