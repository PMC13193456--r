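#' Collinearity filter on candidate variables
#'
#' Computes pairwise Pearson correlations on a table of sampled layer
#' values (typically background samples) and drops one variable of every
#' pair with `|r| > rMax`, preferring to drop the variable that appears
#' later in the priority order. Pairs listed in `keepOverrides` are both
#' retained despite collinearity (mirroring expert-maintained pairs).
#' Constant variables are excluded with a warning.
#'
#' @param samples data.frame/matrix of sampled values, one column per
#'   variable.
#' @param rMax correlation cutoff (default 0.8; pairs above it are
#'   collinear).
#' @param keepOverrides list of 2-element character vectors naming pairs
#'   allowed to remain collinear.
#' @param priority character vector of variable names, highest priority
#'   first; defaults to column order.
#' @return character vector of retained variable names.
#' @examples
#' x <- data.frame(a = rnorm(100))
#' x$b <- x$a + rnorm(100, sd = 0.1)
#' x$c <- rnorm(100)
#' collinearityFilter(x) # drops b
#' @export
collinearityFilter <- function(samples, rMax = 0.8, keepOverrides = list(),
                               priority = colnames(samples)) {
  samples <- as.data.frame(samples)
  if (ncol(samples) < 2) stop("need at least 2 variables", call. = FALSE)
  if (nrow(samples) < 3) stop("need at least 3 samples", call. = FALSE)
  vars <- colnames(samples)
  sds <- vapply(samples, function(x) stats::sd(x, na.rm = TRUE), 0)
  if (any(sds == 0 | is.na(sds))) {
    bad <- vars[sds == 0 | is.na(sds)]
    warning("excluding constant variable(s): ", paste(bad, collapse = ", "))
    vars <- setdiff(vars, bad)
  }
  priority <- intersect(priority, vars)
  overridden <- function(a, b) {
    any(vapply(keepOverrides, function(p) all(c(a, b) %in% p), TRUE))
  }
  r <- stats::cor(samples[vars], use = "pairwise.complete.obs")
  kept <- character()
  for (v in priority) { # greedy in priority order
    clash <- vapply(kept, function(k) {
      abs(r[v, k]) > rMax && !overridden(v, k)
    }, TRUE)
    if (!any(clash)) kept <- c(kept, v)
  }
  kept
}

#' Reduce variables by ranked permutation importance
#'
#' The five best-performing variables are always retained; beyond the
#' top five, a variable is kept only if its permutation importance is at
#' least `piMin` percent and its rank does not exceed
#' `floor(nRecords / rankDivisor)`, balancing predictor count against
#' the number of occurrence records. With fewer than six variables all
#' are kept. Rank ties are broken by variable name order.
#'
#' @param importance named numeric vector of permutation importances
#'   (percent, summing to ~100).
#' @param nRecords number of occurrence records behind the model.
#' @param topK unconditional floor on retained variables (default 5).
#' @param piMin minimum importance in percent (default 1).
#' @param rankDivisor records-per-variable divisor (default 20).
#' @return character vector of retained variable names, in rank order.
#' @examples
#' imp <- c(a = 30, b = 20, c = 15, d = 10, e = 5, f = 0.5, g = 0.4, h = 0.1)
#' reduceVariables(imp, nRecords = 400) # top five only
#' @export
reduceVariables <- function(importance, nRecords, topK = 5, piMin = 1,
                            rankDivisor = 20) {
  if (is.null(names(importance)))
    stop("importance must be a named vector", call. = FALSE)
  if (length(importance) <= topK) return(names(importance))
  o <- order(-importance, names(importance))
  ranked <- importance[o]
  rank <- seq_along(ranked)
  cap <- floor(nRecords / rankDivisor)
  keep <- rank <= topK | (ranked >= piMin & rank <= cap)
  names(ranked)[keep]
}

#' Variable screening report
#'
#' @param samples table of sampled layer values.
#' @param importance named importance vector (percent).
#' @param retained character vector of retained variable names.
#' @return data.frame with `variable`, `max_abs_r`, `r_partner`,
#'   `importance`, `retained`, suitable for writing as CSV.
#' @export
variableReport <- function(samples, importance, retained) {
  r <- stats::cor(as.data.frame(samples), use = "pairwise.complete.obs")
  diag(r) <- 0
  vars <- colnames(r)
  partner <- vars[apply(abs(r), 1, which.max)]
  data.frame(
    variable = vars,
    max_abs_r = apply(abs(r), 1, max),
    r_partner = partner,
    importance = as.numeric(importance[vars]),
    retained = vars %in% retained,
    stringsAsFactors = FALSE
  )
}
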