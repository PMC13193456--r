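#' Build Maxent-style feature definitions and design matrix
#'
#' Linear and quadratic features are always built; pairwise product
#' features only when `allowProduct` is TRUE (they are withheld for
#' data-sparse, naturally restricted units to avoid overfitting);
#' forward and reverse hinge features are placed at `nKnots` evenly
#' spaced knots per variable over the training range. Linear, quadratic
#' and product features are computed on standardized values
#' (z = (x - mean)/sd), hinges on raw values normalized by the knot-to-
#' range distance, so predictions are invariant to affine rescaling of
#' any input variable. The forward hinge whose knot sits at the training
#' maximum (and the reverse hinge at the minimum) is identically zero on
#' the training data.
#'
#' @param X numeric matrix of training values (rows = cells/records,
#'   named columns = variables).
#' @param classes feature classes to build, subset of
#'   `c("linear", "quadratic", "product", "hinge")`.
#' @param allowProduct logical; product features are skipped when FALSE
#'   even if requested in `classes`.
#' @param nKnots hinge knots per variable per direction (default 10).
#' @return list with `def` (feature definition reusable on new data via
#'   [featureMatrix()]) and `M` (the design matrix on `X`).
#' @export
buildFeatures <- function(X, classes = c("linear", "quadratic", "product",
                            "hinge"),
                          allowProduct = TRUE, nKnots = 10) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least two samples to build features", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  classes <- match.arg(classes, several.ok = TRUE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  knots <- lapply(seq_len(ncol(X)), function(j) {
    seq(mins[j], maxs[j], length.out = nKnots)
  })
  names(knots) <- colnames(X)
  def <- list(
    vars = colnames(X), mean = mu, sd = sdv, min = mins, max = maxs,
    classes = classes, allowProduct = allowProduct, knots = knots
  )
  list(def = def, M = featureMatrix(def, X))
}

#' Evaluate a feature definition on new data
#'
#' @param def feature definition from [buildFeatures()].
#' @param X numeric matrix with the definition's variables as columns.
#' @return design matrix with one column per feature.
#' @export
featureMatrix <- function(def, X) {
  X <- as.matrix(X)
  if (!all(def$vars %in% colnames(X)))
    stop("missing variable(s): ",
      paste(setdiff(def$vars, colnames(X)), collapse = ", "), call. = FALSE)
  X <- X[, def$vars, drop = FALSE]
  Z <- sweep(sweep(X, 2, def$mean), 2, def$sd, "/")
  cols <- list()
  nm <- character()
  p <- ncol(X)
  if ("linear" %in% def$classes) {
    for (j in seq_len(p)) {
      cols[[length(cols) + 1L]] <- Z[, j]
      nm <- c(nm, paste0("lin.", def$vars[j]))
    }
  }
  if ("quadratic" %in% def$classes) {
    for (j in seq_len(p)) {
      cols[[length(cols) + 1L]] <- Z[, j]^2
      nm <- c(nm, paste0("quad.", def$vars[j]))
    }
  }
  if ("product" %in% def$classes && def$allowProduct && p >= 2) {
    for (j in seq_len(p - 1)) {
      for (k in (j + 1):p) {
        cols[[length(cols) + 1L]] <- Z[, j] * Z[, k]
        nm <- c(nm, paste0("prod.", def$vars[j], ".", def$vars[k]))
      }
    }
  }
  if ("hinge" %in% def$classes) {
    for (j in seq_len(p)) {
      rng <- def$max[j] - def$min[j]
      if (rng == 0) rng <- 1
      for (k in def$knots[[def$vars[j]]]) {
        den <- def$max[j] - k
        colv <- if (den > 0) pmax(0, X[, j] - k) / den else rep(0, nrow(X))
        cols[[length(cols) + 1L]] <- colv
        nm <- c(nm, sprintf("hingeF.%s.%.6g", def$vars[j], k))
      }
      for (k in def$knots[[def$vars[j]]]) {
        den <- k - def$min[j]
        colv <- if (den > 0) pmax(0, k - X[, j]) / den else rep(0, nrow(X))
        cols[[length(cols) + 1L]] <- colv
        nm <- c(nm, sprintf("hingeR.%s.%.6g", def$vars[j], k))
      }
    }
  }
  M <- do.call(cbind, cols)
  colnames(M) <- nm
  M
}

# clamp columns of X to the training range of def ("no extrapolation")
clampToRange <- function(def, X) {
  X <- as.matrix(X)[, def$vars, drop = FALSE]
  for (j in seq_along(def$vars)) {
    X[, j] <- pmin(pmax(X[, j], def$min[j]), def$max[j])
  }
  X
}
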