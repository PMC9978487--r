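#' Temperature and DOC limitation factors
#'
#' The two factors whose product (times `mu_max`) is the specific DOC
#' uptake rate of free-living bacteria: the Q10 temperature factor
#' `Q10_B^((T-T_ref)/10)` and the cubic Monod DOC limitation
#' `DOC^3/(DOC^3 + X_DOC^3)`. Shares its implementation with the box
#' model, so attribution and simulation cannot drift apart.
#'
#' @param T_c Temperature (degC); vectorised.
#' @param DOC DOC concentration (mmol C m^-3); vectorised.
#' @param p `bact_params`.
#' @return List with `f_T` and `f_DOC`.
#' @examples
#' limitation_terms(20, 10, bact_params()) # f_T = 2.95, f_DOC = 8/9
#' @export
limitation_terms <- function(T_c, DOC, p) {
  list(f_T = temperature_factor(T_c, p$Q10_B, p$T_ref),
       f_DOC = monod_cubic(DOC, p$X_DOC))
}

#' Elementwise first-order Taylor decomposition of DOC uptake changes
#'
#' Decomposes the change in the specific free-living DOC uptake rate
#' `mu_DOC = mu_max * f_T(T) * f_DOC(DOC)` between a baseline and a
#' scenario state into a DOC-control term (change in `f_DOC` weighted by
#' the baseline `f_T`), a temperature-control term (change in `f_T`
#' weighted by the baseline `f_DOC`), and the cross-term residual.
#' Additivity is exact by construction:
#' `total = doc_term + temp_term + residual`, with
#' `residual = mu_max * (f_T' - f_T) * (f_DOC' - f_DOC)`.
#'
#' @param T0,DOC0 Baseline-period mean temperature and DOC; vectorised.
#' @param T1,DOC1 Scenario-period mean temperature and DOC.
#' @param p `bact_params`.
#' @return `data.frame` with columns `total`, `doc_term`, `temp_term`,
#'   `residual` (units of `mu_max`, i.e. d^-1).
#' @export
taylor_terms <- function(T0, DOC0, T1, DOC1, p) {
  b <- limitation_terms(T0, DOC0, p)
  s <- limitation_terms(T1, DOC1, p)
  total <- p$mu_max * (s$f_T * s$f_DOC - b$f_T * b$f_DOC)
  doc_term <- p$mu_max * (s$f_DOC - b$f_DOC) * b$f_T
  temp_term <- p$mu_max * (s$f_T - b$f_T) * b$f_DOC
  # cross term in its analytic form: exactly zero for single-factor
  # changes; equals total - doc - temp up to floating-point association
  data.frame(total = total, doc_term = doc_term, temp_term = temp_term,
             residual = p$mu_max * (s$f_T - b$f_T) * (s$f_DOC - b$f_DOC))
}

#' Period-mean fields of a `field_set`
#'
#' @param fs A `field_set`.
#' @param window Length-2 integer year window (inclusive).
#' @param vars Variables to average (default all).
#' @return Named list of `depth x lat x lon` arrays.
#' @export
period_mean <- function(fs, window, vars = names(fs$vars)) {
  stopifnot(inherits(fs, "field_set"))
  sel <- fs$years >= window[1] & fs$years <= window[2]
  if (!any(sel)) stop("window outside field years", call. = FALSE)
  lapply(fs$vars[vars], function(a)
    apply(a[sel, , , , drop = FALSE], c(2, 3, 4), mean))
}

#' Regional Taylor attribution of DOC-uptake changes
#'
#' Applies [taylor_terms()] to period-mean temperature and DOC fields,
#' weights the specific-rate terms by the baseline free-living biomass
#' field (the biomass factor itself is not decomposed), depth-integrates
#' over the upper layer, annualises, and composites by latitudinal band.
#' Shares of the total are reported for the composited values.
#'
#' With `order = "cellwise"` (default) the decomposition is evaluated
#' per cell and then composited; `order = "composite_first"` composites
#' the period-mean drivers first and decomposes the regional scalars —
#' a sensitivity check on the unstated order of operations.
#'
#' @param baseline Named list with `depth x lat x lon` arrays `T`, `DOC`
#'   and (optionally) `B_DOC`; typically from [period_mean()].
#' @param scenario Named list with arrays `T` and `DOC`.
#' @param grid The `bact_grid` both field sets live on.
#' @param p `bact_params`.
#' @param order `"cellwise"` or `"composite_first"`.
#' @param annualize Multiply daily rates by 365 (default `TRUE`).
#' @param layer Depth-integration layer (m), default `c(0, 107)`.
#' @return `data.frame` (class `taylor_decomposition`) with one row per
#'   region: `region`, `total`, `doc_term`, `temp_term`, `residual`
#'   (mmol C m^-2 y^-1 when `B_DOC` is supplied and `annualize = TRUE`),
#'   and `share_doc`, `share_temp`, `share_residual` (% of total,
#'   summing to 100).
#' @export
taylor_decompose <- function(baseline, scenario, grid, p,
                             order = c("cellwise", "composite_first"),
                             annualize = TRUE, layer = c(0, 107)) {
  order <- match.arg(order)
  stopifnot(inherits(grid, "bact_grid"))
  dims <- c(length(grid$z_centers), length(grid$lat), length(grid$lon))
  for (nm in c("T", "DOC"))
    if (!all(dim(baseline[[nm]]) == dims) || !all(dim(scenario[[nm]]) == dims))
      stop("baseline/scenario arrays do not match the grid", call. = FALSE)
  wB <- if (!is.null(baseline$B_DOC)) baseline$B_DOC else array(1, dims)
  ann <- if (annualize) 365 else 1
  regions <- c("global", "NH", "NI", "LL", "SI", "SO")

  if (order == "cellwise") {
    tt <- taylor_terms(as.vector(baseline$T), as.vector(baseline$DOC),
                       as.vector(scenario$T), as.vector(scenario$DOC), p)
    reduce <- function(term) {
      a <- array(term * as.vector(wB), dims)  # mmol C m^-3 d^-1
      m <- matrix(a, nrow = dims[1])          # depth x (lat*lon)
      v <- depth_reduce(m, grid$z_centers, "integrate", layer) * ann
      composite_stats(matrix(v, dims[2], dims[3]), grid, regions)$mean
    }
    out <- data.frame(region = regions,
                      total = reduce(tt$total),
                      doc_term = reduce(tt$doc_term),
                      temp_term = reduce(tt$temp_term))
  } else {
    comp_driver <- function(a, mode)
      composite_stats(matrix(depth_reduce(matrix(a, nrow = dims[1]),
                                          grid$z_centers, mode,
                                          if (mode == "average") c(10, 107) else layer),
                             dims[2], dims[3]),
                      grid, regions)$mean
    T0 <- comp_driver(baseline$T, "average")
    T1 <- comp_driver(scenario$T, "average")
    D0 <- comp_driver(baseline$DOC, "average")
    D1 <- comp_driver(scenario$DOC, "average")
    W <- comp_driver(wB, "integrate")
    tt <- taylor_terms(T0, D0, T1, D1, p)
    out <- data.frame(region = regions,
                      total = tt$total * W * ann,
                      doc_term = tt$doc_term * W * ann,
                      temp_term = tt$temp_term * W * ann)
  }
  out$residual <- out$total - out$doc_term - out$temp_term
  share <- function(x) ifelse(out$total != 0, 100 * x / out$total, NA_real_)
  out$share_doc <- share(out$doc_term)
  out$share_temp <- share(out$temp_term)
  out$share_residual <- share(out$residual)
  class(out) <- c("taylor_decomposition", "data.frame")
  out
}

#' Arrhenius-type temperature fit of bacterial production
#'
#' Conventional apparent-activation-energy analysis: ordinary least
#' squares of `ln(BP)` on inverse absolute temperature `1/T`. The
#' apparent activation energy is the absolute regression slope times the
#' universal gas constant (R = 8.314 J mol^-1 K^-1), reported in
#' kJ mol^-1; the pre-exponential production `BP0` is `exp(intercept)`.
#'
#' @param BP Bacterial production values (> 0, any consistent unit).
#' @param T_c Temperatures (degC), at least 3 distinct values.
#' @return Object of class `arrhenius_fit`: list with `Ea` (kJ mol^-1),
#'   `BP0`, `r_squared`, `n`, `slope`, and the gas constant `R_gas`.
#' @examples
#' Tc <- c(0, 10, 20, 30)
#' bp <- 2 * exp(-50000 / (8.314 * (Tc + 273.15)))
#' arrhenius_fit(bp, Tc)$Ea # 50
#' @export
arrhenius_fit <- function(BP, T_c) {
  if (length(BP) != length(T_c)) stop("length mismatch", call. = FALSE)
  if (length(BP) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(BP <= 0)) stop("BP must be positive", call. = FALSE)
  if (length(unique(T_c)) < 2) stop("temperatures must vary", call. = FALSE)
  R_gas <- 8.314
  x <- 1 / (T_c + 273.15)
  fit <- stats::lm(log(BP) ~ x)
  sl <- unname(stats::coef(fit)[2])
  tss <- sum((log(BP) - mean(log(BP)))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else NA_real_
  structure(list(Ea = abs(sl) * R_gas / 1000,
                 BP0 = exp(unname(stats::coef(fit)[1])),
                 r_squared = r2,
                 n = length(BP), slope = sl, R_gas = R_gas),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: Ea = %.3g kJ/mol, BP0 = %.3g, r^2 = %.3f, n = %d\n",
              x$Ea, x$BP0, x$r_squared, x$n))
  invisible(x)
}
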