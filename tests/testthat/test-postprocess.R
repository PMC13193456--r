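test_that("cost distance matches closed-form values on simple surfaces", {
  # uniform suitability 0.5 strip: resistance 2 everywhere, each rook
  # step costs 2
  spec <- tinySpec(1, 11)
  strip <- GeoGrid(spec, matrix(0.5, 1, 11))
  occ <- occAt(spec, 1, 1)
  cd <- costDistance(strip, occ)
  expect_equal(gridValues(cd)[1, 1], 0) # source cell
  expect_equal(gridValues(cd)[1, 2], 2)
  expect_equal(gridValues(cd)[1, 11], 20)

  # single diagonal step through perfect habitat costs sqrt(2)
  sq <- GeoGrid(tinySpec(2, 2), matrix(1, 2, 2))
  cd2 <- costDistance(sq, occAt(tinySpec(2, 2), 1, 1))
  expect_equal(gridValues(cd2)[2, 2], sqrt(2))

  # nodata blocks travel; occurrences on nodata are an error
  v <- matrix(1, 3, 3)
  v[, 2] <- NA
  blocked <- GeoGrid(tinySpec(3, 3), v)
  cdb <- costDistance(blocked, occAt(tinySpec(3, 3), 2, 1))
  expect_true(all(is.infinite(gridValues(cdb)[, 3])))
  expect_true(all(is.na(gridValues(cdb)[, 2])))
  expect_error(costDistance(blocked, occAt(tinySpec(3, 3), 2, 2)), "data cell")
})

test_that("cost distance equals brute-force Dijkstra on random grids", {
  set.seed(99)
  for (rep in 1:10) {
    nr <- 15
    v <- matrix(runif(nr * nr, 0.05, 1), nr, nr)
    if (rep > 5) v[sample(nr * nr, 10)] <- NA # holes in half the cases
    spec <- tinySpec(nr, nr)
    g <- GeoGrid(spec, v)
    okCells <- which(!is.na(as.vector(v)))
    src <- sample(okCells, sample(1:3, 1))
    rows <- (src - 1) %% nr + 1
    cols <- (src - 1) %/% nr + 1
    cd <- costDistance(g, occAt(spec, rows, cols))
    oracle <- bruteCostDistance(v, src)
    expect_equal(gridValues(cd), oracle, tolerance = 1e-10)
  }
})

test_that("CDU clipping removes exactly the cells beyond the cut", {
  spec <- tinySpec(1, 10)
  suit <- GeoGrid(spec, matrix(0.8, 1, 10))
  cost <- GeoGrid(spec, matrix(seq(0, 900, by = 100), 1, 10))
  out <- clipByCdu(suit, cost, maxCdu = 500)
  v <- gridValues(out$clipped)
  expect_equal(v[1, 6], 0.8) # cost 500: kept
  expect_equal(v[1, 7], 0) # cost 600: removed
  expect_identical(gridValues(out$raw), gridValues(suit))

  # all costs zero: unchanged
  zero <- GeoGrid(spec, matrix(0, 1, 10))
  expect_identical(gridValues(clipByCdu(suit, zero)$clipped), gridValues(suit))

  # retained count is monotone in the cut
  counts <- vapply(c(100, 500, 1000), function(mc) {
    sum(gridValues(clipByCdu(suit, cost, mc)$clipped) > 0)
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("MU splitting applies the overlap fade-out rule", {
  spec <- tinySpec(1, 1)
  one <- GeoGrid(spec, matrix(0.8, 1, 1))
  mk <- function(x) GeoGrid(spec, matrix(x, 1, 1))

  # equal cost distances of 250: both species downweighted by 50%
  both <- splitMu(one, list(A = mk(250), B = mk(250)))
  expect_equal(gridValues(both$A)[1, 1], 0.4)
  expect_equal(gridValues(both$B)[1, 1], 0.4)

  # cd 100 vs 300: weights 0.75 / 0.25
  skew <- splitMu(one, list(A = mk(100), B = mk(300)))
  expect_equal(gridValues(skew$A)[1, 1], 0.8 * 0.75)
  expect_equal(gridValues(skew$B)[1, 1], 0.8 * 0.25)

  # second species beyond the allowance: winner keeps full weight
  far <- splitMu(one, list(A = mk(100), B = mk(700)))
  expect_equal(gridValues(far$A)[1, 1], 0.8)
  expect_equal(gridValues(far$B)[1, 1], 0)

  # single-species MU is the identity
  single <- splitMu(one, list(A = mk(42)))
  expect_identical(gridValues(single$A), gridValues(one))

  # re-thresholding zeroes downweighted cells below the original cut
  rethr <- splitMu(one, list(A = mk(250), B = mk(250)), threshold = 0.5)
  expect_equal(gridValues(rethr$A)[1, 1], 0) # 0.4 < 0.5
})

test_that("split weights are conserved and dominance is preserved", {
  set.seed(12)
  spec <- tinySpec(12, 12)
  suit <- GeoGrid(spec, matrix(runif(144, 0.2, 1), 12, 12))
  costs <- lapply(1:3, function(i) {
    GeoGrid(spec, matrix(runif(144, 0, 800), 12, 12))
  })
  names(costs) <- c("A", "B", "C")
  out <- splitMu(suit, costs)
  W <- vapply(out, function(g) as.vector(gridValues(g)), numeric(144)) /
    as.vector(gridValues(suit))
  C <- vapply(costs, function(g) as.vector(gridValues(g)), numeric(144))
  for (i in seq_len(144)) {
    o <- order(C[i, ])
    # the minimum-cd species always has the maximal output weight
    expect_equal(unname(which.max(W[i, ])), o[1])
    if (C[i, o[2]] < 500) {
      # pairwise overlap: the two lowest share weight summing to 1
      expect_equal(sum(W[i, o[1:2]]), 1, tolerance = 1e-12)
      expect_equal(unname(W[i, o[3]]), 0)
    } else {
      expect_equal(unname(W[i, o[1]]), 1)
      expect_equal(sum(W[i, -o[1]]), 0)
    }
  }
  expect_error(
    splitMu(suit, list(A = GeoGrid(tinySpec(5, 5), 1))),
    "lattice"
  )
})
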