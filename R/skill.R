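#' Microbial conversion constants
#'
#' Carbon-per-cell and thymidine conversion factors used to translate
#' field measurements into model carbon units. Defaults: 10 fg C cell^-1
#' (conservative open-ocean value, used for time-series stations;
#' gridded climatologies conventionally use 9.1) and 3.0e18 cells
#' produced per mole of 3H-thymidine incorporated (literature range
#' 0.5e18-4.9e18).
#'
#' @param ccf Carbon conversion factor (fg C cell^-1).
#' @param tcf Thymidine conversion factor (cells mol^-1).
#' @return List of class `conversion_constants` with `CCF`, `TCF`,
#'   `C_molar_mass` (12.011 g mol^-1) and the `tcf_range` sensitivity
#'   bounds.
#' @export
conversion_constants <- function(ccf = 10, tcf = 3.0e18) {
  if (ccf <= 0 || tcf <= 0) stop("conversion factors must be positive", call. = FALSE)
  structure(list(CCF = ccf, TCF = tcf, C_molar_mass = 12.011,
                 tcf_range = c(min = 0.5e18, max = 4.9e18)),
            class = "conversion_constants")
}

# cells L^-1 -> mmol C m^-3 multiplier:
# x1e3 (L->m^3), xCCF (fg C), x1e-15 (fg->g), /12.011 (g->mol), x1e3 (->mmol)
abundance_to_biomass_factor <- function(ccf) ccf * 1e-9 / 12.011

# pmol thymidine L^-1 h^-1 -> mmol C m^-3 d^-1 multiplier:
# x1e-12 (pmol->mol), xTCF (cells), x24 (h->d), then cells->carbon as above
thymidine_to_production_factor <- function(tcf, ccf)
  1e-12 * tcf * 24 * abundance_to_biomass_factor(ccf)

#' Convert bacterial abundance to carbon biomass
#'
#' `cells L^-1` to `mmol C m^-3` via a carbon-per-cell conversion factor.
#'
#' @param abundance Bacterial abundance (cells L^-1), >= 0.
#' @param ccf Carbon conversion factor (fg C cell^-1), default 10.
#' @return Carbon biomass (mmol C m^-3).
#' @examples
#' convert_abundance(1e9)            # 0.8326
#' convert_abundance(1e9, ccf = 9.1) # 0.7576
#' @export
convert_abundance <- function(abundance, ccf = 10) {
  if (any(abundance < 0)) stop("abundance must be non-negative", call. = FALSE)
  abundance * abundance_to_biomass_factor(ccf)
}

#' Convert thymidine incorporation to bacterial production
#'
#' `pmol 3H-thymidine L^-1 h^-1` to `mmol C m^-3 d^-1`: incorporation is
#' turned into cell production via the thymidine conversion factor, then
#' into carbon via the carbon-per-cell factor, and scaled to a daily
#' rate. Linear in both factors.
#'
#' @param tdr Thymidine incorporation rate (pmol L^-1 h^-1), >= 0.
#' @param tcf Thymidine conversion factor (cells mol^-1), default 3.0e18.
#' @param ccf Carbon conversion factor (fg C cell^-1), default 10.
#' @return Bacterial production (mmol C m^-3 d^-1).
#' @examples
#' convert_thymidine(5) # 0.2997
#' @export
convert_thymidine <- function(tdr, tcf = 3.0e18, ccf = 10) {
  if (any(tdr < 0)) stop("incorporation rate must be non-negative", call. = FALSE)
  tdr * thymidine_to_production_factor(tcf, ccf)
}

#' Pair model fields with synthetic observations
#'
#' Converts observation records to model units, aggregates them to
#' climatological monthly means (mode `"monthly"`, mirroring
#' climatology-style comparisons) or yearly means per location (mode
#' `"yearly"`), and pairs each aggregate with the co-located model
#' value: the model time-mean over the observed years (monthly mode) or
#' the model value of the matching year (yearly mode). Months or years
#' without observations are dropped.
#'
#' @param model A `field_set` containing `B` (abundance records) and/or
#'   `BP` (thymidine records).
#' @param obs Records from [generate_station_obs()] /
#'   [generate_gridded_obs()] (columns `station`, `lat`, `lon`,
#'   `depth_m`, `quantity`, `value`, and `year` for yearly mode).
#' @param mode `"monthly"` or `"yearly"`.
#' @param constants [conversion_constants()] used to convert `value`.
#' @return `data.frame` of pairs: `station`, `month` or `year`, `obs`,
#'   `model` (both in model units).
#' @export
match_model_obs <- function(model, obs, mode = c("monthly", "yearly"),
                            constants = conversion_constants()) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "field_set"), nrow(obs) > 0)
  g <- model$grid
  q <- unique(obs$quantity)
  if (length(q) != 1) stop("mixed quantities; pair one at a time", call. = FALSE)
  var <- if (q == "abundance") "B" else "BP"
  if (is.null(model$vars[[var]]))
    stop("model field_set lacks variable ", var, call. = FALSE)
  obs$model_units <- if (q == "abundance")
    convert_abundance(obs$value, constants$CCF)
  else convert_thymidine(obs$value, constants$TCF, constants$CCF)

  if (mode == "yearly") {
    if (!any(obs$year %in% model$years))
      stop("no overlap between observation and model years", call. = FALSE)
    obs <- obs[obs$year %in% model$years, ]
    agg <- stats::aggregate(model_units ~ station + lat + lon + depth_m + year,
                            data = obs, FUN = mean)
    agg$model <- mapply(function(la, lo, dm, yr) {
      model$vars[[var]][match(yr, model$years),
                        which.min(abs(g$z_centers - dm)),
                        which.min(abs(g$lat - la)),
                        which.min(abs(g$lon - lo %% 360))]
    }, agg$lat, agg$lon, agg$depth_m, agg$year)
    out <- data.frame(station = agg$station, year = agg$year,
                      obs = agg$model_units, model = agg$model)
  } else {
    yr_sel <- if ("year" %in% names(obs)) {
      keep <- obs$year %in% model$years
      if (!any(keep)) stop("no overlap between observation and model years",
                           call. = FALSE)
      obs <- obs[keep, ]
      unique(obs$year)
    } else model$years
    agg <- stats::aggregate(model_units ~ station + lat + lon + depth_m + month,
                            data = obs, FUN = mean)
    tsel <- model$years %in% yr_sel
    agg$model <- mapply(function(la, lo, dm) {
      mean(model$vars[[var]][tsel,
                             which.min(abs(g$z_centers - dm)),
                             which.min(abs(g$lat - la)),
                             which.min(abs(g$lon - lo %% 360))])
    }, agg$lat, agg$lon, agg$depth_m)
    out <- data.frame(station = agg$station, month = agg$month,
                      obs = agg$model_units, model = agg$model)
  }
  out[order(out$station, out[[2]]), ]
}

#' Univariate model-observation skill scores
#'
#' The standard suite for gridded biogeochemical model evaluation:
#' average bias (model minus observation), average absolute error, root
#' mean square difference and its exact decomposition
#' `RMSD^2 = bias^2 + centered RMSD^2`, Pearson correlation with a
#' two-sided p-value, and the reliability index
#' `RI = exp( sqrt( mean( ln(O/P)^2 ) ) )` — about 68% of predictions
#' fall between `obs/RI` and `obs*RI` for lognormal errors. RI requires
#' strictly positive data and is `NA` (with a warning) otherwise; the
#' correlation is `NA` for constant series or `n < 2`.
#'
#' @param obs,model Numeric vectors of paired observed and predicted
#'   values (or a data.frame from [match_model_obs()] as `obs`).
#' @return Object of class `skill_report`: list with `n`, `bias`, `aae`,
#'   `rmsd`, `crmsd`, `r`, `p_value`, `ri`.
#' @examples
#' skill_scores(c(1, 2, 3), c(1.5, 2, 2.5)) # bias 0, RI 1.29
#' @export
skill_scores <- function(obs, model = NULL) {
  if (is.data.frame(obs)) { model <- obs$model; obs <- obs$obs }
  stopifnot(length(obs) == length(model), length(obs) >= 1)
  d <- model - obs
  rmsd <- sqrt(mean(d^2))
  bias <- mean(d)
  crmsd <- sqrt(max(rmsd^2 - bias^2, 0))
  if (length(obs) >= 2 && stats::sd(obs) > 0 && stats::sd(model) > 0) {
    ct <- stats::cor.test(obs, model)
    r <- unname(ct$estimate); pv <- ct$p.value
  } else { r <- NA_real_; pv <- NA_real_ }
  if (all(obs > 0) && all(model > 0)) {
    ri <- exp(sqrt(mean(log(obs / model)^2)))
  } else {
    warning("non-positive values; reliability index undefined", call. = FALSE)
    ri <- NA_real_
  }
  structure(list(n = length(obs), bias = bias, aae = mean(abs(d)),
                 rmsd = rmsd, crmsd = crmsd, r = r, p_value = pv, ri = ri),
            class = "skill_report")
}

#' @export
print.skill_report <- function(x, ...) {
  cat(sprintf(paste0("skill (n=%d): bias %.4g | AAE %.4g | RMSD %.4g | ",
                     "cRMSD %.4g | r %.3f (p %.3g) | RI %.4g\n"),
              x$n, x$bias, x$aae, x$rmsd, x$crmsd, x$r, x$p_value, x$ri))
  invisible(x)
}

#' Thymidine-conversion-factor sensitivity of a production ratio
#'
#' Rescales a model/observation overestimation factor obtained under one
#' thymidine conversion factor to an alternative factor by direct
#' proportionality, `adjusted = baseline * tcf_alt / tcf_base` — the
#' printed arithmetic of the source analysis (a strict
#' observation-rescaling argument would invert the ratio; see the
#' methods vignette).
#'
#' @param baseline_ratio Model/obs ratio under `tcf_base` (> 0).
#' @param tcf_alt Alternative thymidine conversion factor (cells mol^-1).
#' @param tcf_base Baseline thymidine conversion factor (cells mol^-1).
#' @return The adjusted overestimation factor.
#' @examples
#' tcf_sensitivity(3.6, 0.5e18, 3.0e18) # 0.6
#' tcf_sensitivity(3.6, 4.9e18, 3.0e18) # 5.88
#' @export
tcf_sensitivity <- function(baseline_ratio, tcf_alt, tcf_base = 3.0e18) {
  if (any(c(baseline_ratio, tcf_alt, tcf_base) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  baseline_ratio * tcf_alt / tcf_base
}
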