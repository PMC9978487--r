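#' Trapezoidal depth integral or average over a layer
#'
#' Reduces a profile sampled at depth-level centres to a layer scalar by
#' the trapezoidal rule. Values at the layer boundaries are obtained by
#' linear interpolation between the straddling levels; where a boundary
#' lies outside the sampled range (e.g. the sea surface above the first
#' level centre) the nearest level value is extended as a constant.
#' `mode = "integrate"` returns the integral (e.g. mmol C m^-2 from
#' mmol C m^-3); `mode = "average"` divides by the layer thickness.
#'
#' The reduction is linear in the profile values, so it is exact for
#' profiles linear in depth.
#'
#' @param values Numeric vector of values at `depths`, or a matrix with
#'   one row per depth level (columns = cells) reduced column-wise.
#' @param depths Depth-level centres (m), strictly increasing.
#' @param mode `"integrate"` or `"average"`.
#' @param layer Length-2 numeric, `c(z_top, z_bot)`; defaults to the
#'   upper-ocean layer `c(0, 107)`.
#' @return Scalar (vector input) or vector of length `ncol(values)`.
#' @examples
#' depth_reduce(rep(3, 5), c(10, 30, 50, 80, 105))            # 321 = 3*107
#' depth_reduce(2 + 0.04 * c(0, 50, 100), c(0, 50, 100),
#'              layer = c(0, 100))                            # 400
#' @export
depth_reduce <- function(values, depths, mode = c("integrate", "average"),
                         layer = c(0, 107)) {
  mode <- match.arg(mode)
  stopifnot(length(layer) == 2, layer[1] < layer[2])
  if (is.unsorted(depths, strictly = TRUE))
    stop("depths must be strictly increasing", call. = FALSE)
  w <- depth_weights(depths, layer)
  if (is.matrix(values)) {
    if (nrow(values) != length(depths))
      stop("nrow(values) must equal length(depths)", call. = FALSE)
    out <- as.vector(crossprod(values, w))
  } else {
    if (length(values) != length(depths))
      stop("values and depths must have the same length", call. = FALSE)
    out <- sum(w * values)
  }
  if (mode == "average") out <- out / (layer[2] - layer[1]) else out
}

# Trapezoid weight vector over level centres for the integral across
# `layer`, with linear interpolation to the boundaries (constant
# extension beyond the sampled range). Errors unless >= 2 levels
# intersect the layer.
depth_weights <- function(depths, layer) {
  inside <- depths > layer[1] & depths < layer[2]
  if (sum(depths >= layer[1] & depths <= layer[2]) < 2)
    stop("fewer than 2 depth levels intersect the layer", call. = FALSE)
  n <- length(depths)
  # augmented nodes: boundary, interior centres, boundary
  za <- c(layer[1], depths[inside], layer[2])
  m <- length(za)
  # interpolation matrix L (m x n): augmented value = L %*% profile
  L <- matrix(0, m, n)
  L[cbind(seq_len(m)[-c(1, m)], which(inside))] <- 1
  for (k in c(1L, m)) {
    zb <- za[k]
    if (zb <= depths[1]) L[k, 1] <- 1
    else if (zb >= depths[n]) L[k, n] <- 1
    else {
      i <- findInterval(zb, depths)
      a <- (depths[i + 1] - zb) / (depths[i + 1] - depths[i])
      L[k, i] <- a; L[k, i + 1] <- 1 - a
    }
  }
  dz <- diff(za)
  wa <- c(dz / 2, 0) + c(0, dz / 2)
  as.vector(crossprod(L, wa))
}

#' Area-weighted regional composite statistics
#'
#' Composites a depth-reduced 2-D (or 2-D-per-year) field into per-region
#' means with standard errors: the mean is area-weighted (cosine-latitude
#' weights renormalised within the region), while the standard error is
#' the unweighted spatial standard deviation across the region's ocean
#' cells divided by `sqrt(n)` — i.e. `n` counts grid cells, matching the
#' cell-count semantics of observational composite tables.
#'
#' @param x Numeric `n_lat x n_lon` matrix, or a 3-D array
#'   `year x n_lat x n_lon` for a yearly series.
#' @param grid A [build_grid()] object.
#' @param regions Character vector of region ids among
#'   `c("global", "NH", "NI", "LL", "SI", "SO")`; default all six.
#' @param years Optional year labels for the series case.
#' @return `data.frame` with columns `region`, `year` (NA for a single
#'   field), `mean`, `se`, `n`.
#' @export
composite_stats <- function(x, grid, regions = c("global", "NH", "NI", "LL", "SI", "SO"),
                            years = NULL) {
  stopifnot(inherits(grid, "bact_grid"))
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  if (is.matrix(x)) x <- array(x, dim = c(1, nlat, nlon))
  stopifnot(length(dim(x)) == 3, dim(x)[2] == nlat, dim(x)[3] == nlon)
  ny <- dim(x)[1]
  if (is.null(years)) years <- if (ny == 1) NA_integer_ else seq_len(ny)
  cell_region <- matrix(grid$region, nlat, nlon)
  out <- list()
  for (reg in regions) {
    sel <- grid$ocean & (if (reg == "global") TRUE else cell_region == reg)
    n <- sum(sel)
    if (n == 0) stop("empty region: ", reg, call. = FALSE)
    w <- grid$weights[sel]
    w <- w / sum(w)
    for (iy in seq_len(ny)) {
      v <- x[iy, , ][sel]
      if (anyNA(v)) stop("NaN/NA in ocean cells of region ", reg, call. = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        region = reg, year = years[iy],
        mean = sum(w * v),
        se = if (n > 1) stats::sd(v) / sqrt(n) else 0,
        n = n)
    }
  }
  do.call(rbind, out)
}

#' Baseline-vs-scenario change metrics for a regional series
#'
#' Summarises a yearly regional mean series into the standard projection
#' change metrics: baseline-window mean, scenario-window mean, absolute
#' difference (scenario minus baseline), ratio-based percent change
#' `100 * (scenario/baseline - 1)` (NA when the baseline mean is 0), and
#' the ordinary-least-squares linear trend expressed per decade.
#'
#' @param series `data.frame` with columns `year` and `mean` (one
#'   region/variable at a time).
#' @param baseline Length-2 integer window, default `c(1990, 2013)`.
#' @param scenario Length-2 integer window, default `c(2076, 2099)`.
#' @return One-row `data.frame`: `baseline_mean`, `scenario_mean`,
#'   `difference`, `percent_change`, `trend_per_decade`.
#' @examples
#' s <- data.frame(year = 1990:2099, mean = seq(57, 60, length.out = 110))
#' change_metrics(s)
#' @export
change_metrics <- function(series, baseline = c(1990, 2013),
                           scenario = c(2076, 2099)) {
  stopifnot(all(c("year", "mean") %in% names(series)))
  for (w in list(baseline, scenario))
    if (!any(series$year >= w[1] & series$year <= w[2]))
      stop("window ", w[1], "-", w[2], " outside series span", call. = FALSE)
  bm <- mean(series$mean[series$year >= baseline[1] & series$year <= baseline[2]])
  sm <- mean(series$mean[series$year >= scenario[1] & series$year <= scenario[2]])
  slope <- unname(stats::coef(stats::lm(mean ~ year, data = series))[2]) * 10
  data.frame(baseline_mean = bm, scenario_mean = sm,
             difference = sm - bm,
             percent_change = if (bm != 0) 100 * (sm / bm - 1) else NA_real_,
             trend_per_decade = slope)
}
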