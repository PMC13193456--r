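#' Fit a Maxent-style L1-penalized Gibbs niche model
#'
#' The model is the Gibbs distribution p(x) = exp(w . f(x)) / Z over the
#' union of background and presence cells; the weights maximize the
#' penalized log-likelihood of the presences,
#' mean_i w . f(x_i) - log Z - sum_j lambda_j |w_j|,
#' a convex problem solved by proximal Newton: each outer iteration
#' replaces the log-normalizer with its local quadratic model and solves
#' the resulting L1-penalized quadratic by cyclic coordinate descent,
#' with step halving on the true objective. Per-feature penalties
#' default to lambda_j = beta * sd(f_j at presences) / sqrt(n_presences),
#' in the spirit of Maxent's default regularization. The logistic output
#' is plogis(eta + H) with eta = w . f(x) - log Z and H the entropy of
#' the fitted density, i.e. the default logistic output with prevalence
#' 0.5. The balance threshold (see [balanceThreshold()]) is computed on
#' the training data and stored on the model.
#'
#' @param presX numeric matrix of environmental values at presence
#'   cells (named columns).
#' @param bgX numeric matrix of values at background cells (same
#'   columns).
#' @param classes feature classes, see [buildFeatures()].
#' @param allowProduct allow product features (withheld for data-sparse
#'   restricted units).
#' @param nKnots hinge knots per variable per direction.
#' @param beta regularization multiplier (default 1).
#' @param tol convergence tolerance on the objective change (1e-8).
#' @param maxIter maximum optimizer iterations (500).
#' @param computeThreshold compute and store the balance threshold
#'   (default TRUE).
#' @return a [NicheModel-class].
#' @export
fitNicheModel <- function(presX, bgX,
                          classes = c("linear", "quadratic", "product", "hinge"),
                          allowProduct = TRUE, nKnots = 10, beta = 1,
                          tol = 1e-8, maxIter = 500,
                          computeThreshold = TRUE) {
  presX <- as.matrix(presX)
  bgX <- as.matrix(bgX)
  if (nrow(presX) < 2) stop("need at least 2 presences", call. = FALSE)
  if (nrow(bgX) < 10) stop("need at least 10 background rows", call. = FALSE)
  n <- nrow(presX)
  allX <- rbind(presX, bgX)
  fb <- buildFeatures(allX,
    classes = classes, allowProduct = allowProduct,
    nKnots = nKnots
  )
  def <- fb$def
  M <- fb$M
  Mpres <- M[seq_len(n), , drop = FALSE]
  # penalty floors keep features that are flat at the presences (zero
  # sample sd) from becoming effectively unpenalized; hinges get the
  # conservative floor of 0.5 (the sd ceiling of a [0,1] feature, and
  # the hinge regularization constant of the reference implementation)
  sdp <- apply(Mpres, 2, stats::sd)
  sdFloor <- ifelse(grepl("^hinge", colnames(M)), 0.5, 0.05)
  lambda <- beta * pmax(sdp, sdFloor) / sqrt(n)
  fbar <- colMeans(Mpres)

  smooth <- function(w) { # -presence term + log normalizer
    eta <- drop(M %*% w)
    mx <- max(eta)
    lz <- mx + log(sum(exp(eta - mx)))
    list(val = -sum(fbar * w) + lz, eta = eta, logZ = lz)
  }
  softThresh <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

  nf <- ncol(M)
  w <- numeric(nf)
  sm <- smooth(w)
  obj <- sm$val
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    p <- exp(sm$eta - sm$logZ)
    Ep <- drop(crossprod(M, p))
    g <- Ep - fbar
    # Hessian of log Z: F' diag(p) F - (F'p)(F'p)', damped for stability
    H <- crossprod(M * sqrt(p)) - tcrossprod(Ep)
    # damping: collinear features (e.g. the hinge at the training
    # minimum vs the linear term) make H rank-deficient
    diag(H) <- diag(H) + 1e-6 * max(diag(H), 1)
    # L1-penalized quadratic subproblem by cyclic coordinate descent
    d <- numeric(nf)
    Hd <- numeric(nf)
    hjj <- diag(H)
    for (pass in seq_len(200)) {
      delta <- 0
      for (j in seq_len(nf)) {
        r <- g[j] + Hd[j] - hjj[j] * d[j]
        zOld <- w[j] + d[j]
        z <- softThresh(hjj[j] * w[j] - r, lambda[j]) / hjj[j]
        if (z != zOld) {
          Hd <- Hd + H[, j] * (z - zOld)
          delta <- max(delta, abs(z - zOld))
          d[j] <- z - w[j]
        }
      }
      if (delta < 1e-10) break
    }
    # trust region: the quadratic model is only local
    dmax <- max(abs(d))
    if (dmax > 5) d <- d * (5 / dmax)
    # step halving on the true objective; an exhausted line search
    # means we are at the numerical optimum
    step <- 1
    exhausted <- FALSE
    repeat {
      wNew <- w + step * d
      smNew <- smooth(wNew)
      objNew <- smNew$val + sum(lambda * abs(wNew))
      if (objNew <= obj + 1e-12) break
      step <- step / 2
      if (step < 1e-8) {
        exhausted <- TRUE
        break
      }
    }
    if (exhausted) {
      converged <- TRUE
      break
    }
    done <- abs(obj - objNew) < tol
    w <- wNew
    sm <- smNew
    obj <- objNew
    if (done) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("optimizer did not converge within ", maxIter,
      " iterations (objective still changing)", call. = FALSE)
  p <- exp(sm$eta - sm$logZ)
  entropy <- -sum(ifelse(p > 0, p * log(p), 0))
  model <- new("NicheModel",
    features = def, weights = stats::setNames(drop(w), colnames(M)),
    logZ = sm$logZ, entropy = entropy, lambda = lambda,
    trainRange = rbind(min = def$min, max = def$max),
    threshold = NA_real_, cvAUC = numeric(), importance = numeric(),
    converged = TRUE, iterations = iter
  )
  if (computeThreshold) {
    model@threshold <- balanceThreshold(model, presX, allX)
  }
  model
}

#' Predict suitability from a fitted model
#'
#' Environmental values are clamped to the training range of every
#' variable before features are evaluated, so the model never
#' extrapolates beyond conditions seen in training. Nodata (NA) cells
#' propagate to the output.
#'
#' @param model a [NicheModel-class].
#' @param newdata either a numeric matrix with the model variables as
#'   named columns, or a named list of aligned [GeoGrid-class] layers.
#' @return numeric vector of logistic suitability in (0,1), or a
#'   [GeoGrid-class] when `newdata` is a layer stack.
#' @export
predictSuitability <- function(model, newdata) {
  def <- model@features
  if (is.list(newdata) && !is.data.frame(newdata) &&
    methods::is(newdata[[1]], "GeoGrid")) {
    missing <- setdiff(def$vars, names(newdata))
    if (length(missing))
      stop("stack is missing variable(s): ",
        paste(missing, collapse = ", "), call. = FALSE)
    for (g in newdata[-1]) stopIfMisaligned(newdata[[1]], g)
    spec <- newdata[[1]]@spec
    X <- vapply(def$vars, function(v) as.vector(newdata[[v]]@values),
      numeric(spec@nRows * spec@nCols)
    )
    colnames(X) <- def$vars
    out <- rep(NA_real_, nrow(X))
    ok <- stats::complete.cases(X)
    if (any(ok)) out[ok] <- predictSuitability(model, X[ok, , drop = FALSE])
    return(GeoGrid(spec, matrix(out, spec@nRows, spec@nCols)))
  }
  X <- clampToRange(def, newdata)
  M <- featureMatrix(def, X)
  eta <- drop(M %*% model@weights) - model@logZ
  unname(stats::plogis(eta + model@entropy))
}

#' Balance threshold of a fitted model
#'
#' Chooses the threshold t* minimizing
#' `6 * trainingOmission(t) + 0.04 * cumulative(t) + 1.6 * fractionalPredictedArea(t)`
#' over all observed suitability values, where cumulative(t) is the
#' percentage of the raw Gibbs density falling below t (the
#' cumulative-format value) and the predicted area is the fraction of
#' evaluation cells at or above t. This is the "balance training
#' omission, predicted area and threshold" rule.
#'
#' @param model a [NicheModel-class].
#' @param presX matrix of environmental values at training presences.
#' @param evalX matrix of values at the evaluation (background +
#'   presence) cells.
#' @return the threshold on the logistic output.
#' @export
balanceThreshold <- function(model, presX, evalX) {
  presScore <- predictSuitability(model, presX)
  evalScore <- predictSuitability(model, evalX)
  M <- featureMatrix(model@features, clampToRange(model@features, evalX))
  eta <- drop(M %*% model@weights)
  praw <- exp(eta - model@logZ)
  praw <- praw / sum(praw)
  cand <- sort(unique(c(presScore, evalScore)))
  om <- vapply(cand, function(t) mean(presScore < t), 0)
  area <- vapply(cand, function(t) mean(evalScore >= t), 0)
  cum <- vapply(cand, function(t) 100 * sum(praw[evalScore < t]), 0)
  objective <- 6 * om + 0.04 * cum + 1.6 * area
  cand[which.min(objective)]
}

#' Threshold a suitability grid and rescale to 0-1
#'
#' Cells below the threshold are set to 0; surviving values are divided
#' by their maximum so the output peaks at 1, making maps of different
#' species (with different thresholds) comparable.
#'
#' @param suit a suitability [GeoGrid-class].
#' @param threshold the balance threshold (or any cutoff).
#' @return a [GeoGrid-class]; all-zero (with a warning) when no cell
#'   survives.
#' @export
thresholdAndRescale <- function(suit, threshold) {
  v <- suit@values
  v[!is.na(v) & v < threshold] <- 0
  mx <- suppressWarnings(max(v[!is.na(v) & v > 0]))
  if (!is.finite(mx)) {
    warning("no cell at or above the threshold; returning all-zero grid")
    return(GeoGrid(suit@spec, v))
  }
  v[!is.na(v) & v > 0] <- v[!is.na(v) & v > 0] / mx
  GeoGrid(suit@spec, v)
}

#' Repeated-split cross-validation AUCs
#'
#' Runs `k` independent random 70/30 presence splits (the background is
#' shared between training and testing), refits the model on each
#' training split and scores the held-out presences against the
#' background with rank-based AUC.
#'
#' @param presX,bgX presence/background environmental matrices.
#' @param k number of splits (default 10).
#' @param trainFrac training fraction (default 0.7).
#' @param seed integer seed.
#' @param ... passed to [fitNicheModel()].
#' @return numeric vector of `k` test AUCs.
#' @export
crossValidate <- function(presX, bgX, k = 10, trainFrac = 0.7, seed = 1, ...) {
  presX <- as.matrix(presX)
  n <- nrow(presX)
  nTrain <- floor(trainFrac * n)
  if (nTrain < 2 || nTrain >= n)
    stop("too few presences (", n, ") for a ", trainFrac, " split", call. = FALSE)
  set.seed(seed)
  vapply(seq_len(k), function(i) {
    idx <- sample.int(n, nTrain)
    fit <- fitNicheModel(presX[idx, , drop = FALSE], bgX,
      computeThreshold = FALSE, ...
    )
    aucScore(
      predictSuitability(fit, presX[-idx, , drop = FALSE]),
      predictSuitability(fit, bgX)
    )
  }, 0)
}

#' Permutation importance of model variables
#'
#' Each variable's column is permuted across the presence + background
#' rows; the drop in training AUC (averaged over `nPerm` permutations,
#' negative drops clipped at zero) is normalized so importances sum to
#' 100. Variables whose features all carry zero weight get importance 0.
#'
#' @param model a [NicheModel-class].
#' @param presX,bgX training matrices.
#' @param nPerm permutations per variable (default 3).
#' @param seed integer seed.
#' @return named numeric vector summing to 100 (all zeros for a null
#'   model with no discriminating variables).
#' @export
permutationImportance <- function(model, presX, bgX, nPerm = 3, seed = 1) {
  presX <- as.matrix(presX)
  bgX <- as.matrix(bgX)
  n <- nrow(presX)
  allX <- rbind(presX, bgX)
  base <- aucScore(
    predictSuitability(model, presX),
    predictSuitability(model, bgX)
  )
  set.seed(seed)
  vars <- model@features$vars
  drops <- vapply(vars, function(v) {
    mean(vapply(seq_len(nPerm), function(r) {
      perm <- allX
      perm[, v] <- perm[sample.int(nrow(perm)), v]
      sc <- predictSuitability(model, perm)
      base - aucScore(sc[seq_len(n)], sc[-seq_len(n)])
    }, 0))
  }, 0)
  drops <- pmax(drops, 0)
  tot <- sum(drops)
  if (tot <= 0) {
    return(stats::setNames(rep(0, length(vars)), vars))
  }
  100 * drops / tot
}
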