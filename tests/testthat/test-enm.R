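# fitting uses the small synthetic world; presences come from a known
# logistic truth so recovery can be checked against it

test_that("null data yields a shrunken, near-constant model", {
  # cleanest null: presence and background share the same distribution
  # exactly (identical sets) -> the penalized fit finds no signal at all
  set.seed(10)
  B <- cbind(a = rnorm(400), b = rnorm(400))
  m <- fitNicheModel(B, B)
  expect_true(all(abs(m@weights) <= 0.05))
  sc <- predictSuitability(m, B)
  expect_lt(diff(range(sc)), 0.2)
  # sampled null: presences drawn from the background distribution
  # discriminate at chance level only
  # (in-sample scoring is slightly optimistic, hence the one-sided bound)
  X <- cbind(a = rnorm(150), b = rnorm(150))
  m2 <- fitNicheModel(X, B)
  expect_lt(
    aucScore(predictSuitability(m2, X), predictSuitability(m2, B)),
    0.65
  )
})

test_that("the Gibbs density normalizes and the model recovers a single driver", {
  spec <- tinySpec(50, 50)
  stack <- genEnvStack(spec, 2, seed = 21)
  truth <- genTrueSuitability(stack, TruthModel(c(3, 0), intercept = -1))
  occs <- snapOccurrences(genOccurrences(truth, 500, seed = 22), spec)
  presCells <- cellOf(spec, occs@lon, occs@lat)
  envAt <- function(cells) {
    X <- vapply(stack, function(g) g@values[cells], numeric(nrow(cells)))
    colnames(X) <- names(stack)
    X
  }
  presX <- envAt(presCells)
  set.seed(23)
  bgCells <- as.matrix(cellCenters(spec)[sample(2500, 1200), c("row", "col")])
  bgX <- envAt(bgCells)
  m <- fitNicheModel(presX, bgX)

  # raw Gibbs probabilities over the training set sum to 1
  M <- featureMatrix(m@features, rbind(presX, bgX))
  praw <- exp(drop(M %*% m@weights) - m@logZ)
  expect_equal(sum(praw), 1, tolerance = 1e-8)

  suit <- predictSuitability(m, stack)
  rho <- cor(as.vector(gridValues(suit)), as.vector(gridValues(truth)),
    method = "spearman"
  )
  expect_gte(rho, 0.9)

  # the uninformative layer earns ~no importance; the driver dominates
  imp <- permutationImportance(m, presX, bgX, seed = 1)
  expect_equal(sum(imp), 100, tolerance = 1e-6)
  expect_gte(imp[["env1"]], 90)

  # stronger penalty cannot increase the active set
  m10 <- fitNicheModel(presX, bgX, beta = 10)
  expect_lte(sum(m10@weights != 0), sum(m@weights != 0))

  # prediction is invariant to affine rescaling of an input variable
  stack2 <- stack
  stack2$env1 <- GeoGrid(spec, gridValues(stack$env1) * 40 + 7)
  presX2 <- presX
  presX2[, "env1"] <- presX2[, "env1"] * 40 + 7
  bgX2 <- bgX
  bgX2[, "env1"] <- bgX2[, "env1"] * 40 + 7
  m2 <- fitNicheModel(presX2, bgX2)
  expect_equal(
    gridValues(predictSuitability(m2, stack2)),
    gridValues(suit),
    tolerance = 1e-6
  )
})

test_that("prediction clamps to the training range and propagates nodata", {
  w <- smallWorld()
  m <- fitNicheModel(w$presX, w$bgX, allowProduct = FALSE)
  # in-sample rows score identically through the grid path
  inSample <- predictSuitability(m, w$presX)
  expect_equal(
    predictSuitability(m, w$presX[3, , drop = FALSE]),
    inSample[3]
  )
  # values above the training max score as at the max ("no extrapolation")
  atMax <- rbind(m@trainRange["max", ])
  beyond <- atMax + 100
  expect_equal(
    predictSuitability(m, beyond),
    predictSuitability(m, atMax)
  )
  # nodata propagates through stack prediction
  stackNA <- w$stack
  v <- gridValues(stackNA$env1)
  v[5, 7] <- NA
  stackNA$env1 <- GeoGrid(w$spec, v)
  suit <- predictSuitability(m, stackNA)
  expect_true(is.na(gridValues(suit)[5, 7]))
  expect_false(anyNA(gridValues(suit)[-5, ]))
  # missing variable is a named error
  expect_error(predictSuitability(m, w$stack[-1]), "env1")
})

test_that("cross-validation returns k test AUCs that beat chance on real signal", {
  w <- smallWorld()
  aucs <- crossValidate(w$presX, w$bgX, k = 5, seed = 31,
    allowProduct = FALSE, nKnots = 5
  )
  expect_length(aucs, 5)
  expect_gt(mean(aucs), 0.6)
  expect_error(
    crossValidate(w$presX[1:2, ], w$bgX, k = 2),
    "too few presences"
  )
})

test_that("cross-validation on separable data scores near-perfect AUC", {
  spec <- tinySpec(40, 40)
  stack <- genEnvStack(spec, 2, seed = 51)
  truth <- genTrueSuitability(stack, TruthModel(c(3, 0), intercept = -1))
  # separable construction: presences only from the top of the truth
  # surface
  top <- GeoGrid(spec, (gridValues(truth) >= quantile(gridValues(truth), 0.97)) * 1)
  occs <- snapOccurrences(genOccurrences(top, 200, seed = 52), spec)
  envAt <- function(cells) {
    X <- vapply(stack, function(g) g@values[cells], numeric(nrow(cells)))
    colnames(X) <- names(stack)
    X
  }
  presX <- envAt(cellOf(spec, occs@lon, occs@lat))
  set.seed(53)
  bgX <- envAt(as.matrix(cellCenters(spec)[sample(1600, 800), c("row", "col")]))
  aucs <- crossValidate(presX, bgX, k = 5, seed = 54, nKnots = 5)
  expect_gt(mean(aucs), 0.95)
})

test_that("random scores sit at chance AUC", {
  set.seed(6)
  expect_equal(
    aucScore(runif(500), runif(2000)), 0.5,
    tolerance = 0.1
  )
})

test_that("the balance threshold matches exhaustive enumeration", {
  w <- smallWorld()
  m <- fitNicheModel(w$presX[1:40, ], w$bgX, allowProduct = FALSE, nKnots = 5)
  presScore <- predictSuitability(m, w$presX[1:40, ])
  evalX <- rbind(w$presX[1:40, ], w$bgX)
  evalScore <- predictSuitability(m, evalX)
  M <- featureMatrix(m@features, evalX)
  praw <- exp(drop(M %*% m@weights) - m@logZ)
  praw <- praw / sum(praw)
  # brute force over every observed value
  cand <- sort(unique(c(presScore, evalScore)))
  obj <- sapply(cand, function(t) {
    6 * mean(presScore < t) + 0.04 * 100 * sum(praw[evalScore < t]) +
      1.6 * mean(evalScore >= t)
  })
  expect_equal(m@threshold, cand[which.min(obj)])
})

test_that("thresholding zeroes sub-threshold cells and rescales to max 1", {
  g <- gridOf(seq(0, 1, length.out = 25), 5, 5)
  thr <- thresholdAndRescale(g, 0.4)
  v <- gridValues(thr)
  expect_equal(max(v), 1)
  expect_true(all(v[gridValues(g) < 0.4] == 0))
  # order preserved among survivors
  surv <- gridValues(g) >= 0.4
  expect_equal(order(v[surv]), order(gridValues(g)[surv]))
  expect_warning(
    zero <- thresholdAndRescale(g, 2),
    "all-zero"
  )
  expect_true(all(gridValues(zero) == 0))
})
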