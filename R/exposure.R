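#' Snake-Human Overlap Index (SHOI)
#'
#' SHOI is habitat suitability multiplied by the natural logarithm of
#' human population density, the basic prerequisite map for human-snake
#' conflict: high where a species' habitat and people coincide. The
#' logarithm is shifted by one, `SHOI = suit * ln(1 + pop)`, so that the
#' index is zero (not undefined) in unpopulated cells and never negative
#' below one person per cell.
#'
#' @param suit suitability [GeoGrid-class] (0 where unsuitable).
#' @param pop population-density [GeoGrid-class] (people per grid cell,
#'   non-negative).
#' @return a [GeoGrid-class] of SHOI values; nodata propagates.
#' @examples
#' spec <- GridSpec(0, 1, 2, 2)
#' shoi(GeoGrid(spec, 0.5), GeoGrid(spec, 99)) # 0.5 * ln(100)
#' @export
shoi <- function(suit, pop) {
  stopIfMisaligned(suit, pop, "suitability and population grids")
  pv <- pop@values
  if (any(!is.na(pv) & pv < 0))
    stop("population density must be non-negative", call. = FALSE)
  GeoGrid(suit@spec, suit@values * log1p(pv))
}

#' Cellwise summaries across species grids
#'
#' `mode = "max"` gives the species-group summary (the cellwise maximum
#' suitability of any member, appropriate for closely related species
#' whose suitability is not additive in contact zones); `mode = "sum"`
#' gives cumulative surfaces (summed suitability or SHOI across groups).
#'
#' @param suits non-empty list of aligned [GeoGrid-class] grids.
#' @param mode `"max"` or `"sum"`.
#' @return a [GeoGrid-class].
#' @export
groupSummary <- function(suits, mode = c("max", "sum")) {
  mode <- match.arg(mode)
  if (length(suits) == 0) stop("empty grid list", call. = FALSE)
  gridApply(suits, mode)
}

#' Rank species by total SHOI within regions
#'
#' Sums each species' SHOI surface over the cells of each region and
#' ranks species within regions by that total — the "which species
#' drive human exposure where" table.
#'
#' @param shois named list of per-species SHOI [GeoGrid-class] grids.
#' @param regionMask [GeoGrid-class] of region codes (cells outside all
#'   regions NA or 0), aligned with the SHOI grids.
#' @param regionNames optional named character vector mapping codes to
#'   labels.
#' @return data.frame with `region`, `species`, `totalShoi`, `rank`
#'   (1 = highest within region), ordered by region then rank.
#' @export
shoiRanking <- function(shois, regionMask, regionNames = NULL) {
  if (length(shois) == 0) stop("empty grid list", call. = FALSE)
  if (is.null(names(shois))) names(shois) <- paste0("sp", seq_along(shois))
  for (g in shois) stopIfMisaligned(regionMask, g)
  codes <- gridValues(regionMask)
  regs <- sort(unique(codes[!is.na(codes) & codes != 0]))
  rows <- list()
  for (rg in regs) {
    inRegion <- !is.na(codes) & codes == rg
    tot <- vapply(shois, function(g) {
      sum(g@values[inRegion], na.rm = TRUE)
    }, 0)
    label <- if (!is.null(regionNames)) regionNames[[as.character(rg)]] else rg
    o <- order(-tot, names(tot))
    rows[[length(rows) + 1L]] <- data.frame(
      region = label, species = names(tot)[o], totalShoi = unname(tot[o]),
      rank = seq_along(tot), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Species richness from thresholded suitability grids
#'
#' @param suits list of aligned thresholded [GeoGrid-class] grids (one
#'   per species; suitable means value > 0).
#' @return a [GeoGrid-class] of per-cell species counts.
#' @export
richness <- function(suits) {
  if (length(suits) == 0) stop("empty grid list", call. = FALSE)
  for (g in suits[-1]) stopIfMisaligned(suits[[1]], g)
  spec <- suits[[1]]@spec
  counts <- Reduce(`+`, lapply(suits, function(g) {
    v <- g@values
    out <- matrix(0, nrow(v), ncol(v))
    out[!is.na(v) & v > 0] <- 1
    out
  }))
  GeoGrid(spec, counts)
}
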