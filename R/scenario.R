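# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards (bit-identical repeatability
# without clobbering the session RNG).
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic climate scenario
#'
#' Describes the stated world a synthetic gridded experiment emulates:
#' per-region baseline means and end-of-century (2076-2099) targets for
#' each environmental variable, the trend ramp, vertical profile shapes,
#' spatial-anomaly amplitude and AR(1) interannual noise. Defaults for
#' temperature, DOC and POC are the regional composites of the packaged
#' table-1 fixture (baseline row and the row of the requested SSP);
#' dissolved oxygen defaults to a uniform oxic 250 mmol O2 m^-3, and
#' microzooplankton/phytoplankton to smooth trend-free fields with
#' low-latitude minima.
#'
#' Stocks given per m^2 (over the upper 107 m) are converted to surface
#' concentrations by dividing by the shape-weighted layer thickness of
#' the target grid at generation time; temperature is interpreted as the
#' layer average. The linear trend starts in 2015 and is scaled so the
#' 2076-2099 window mean equals the target exactly (the ramp reaches
#' ~1.16 by 2099; see the methods vignette).
#'
#' @param scenario One of `"historical"`, `"ssp126"`, `"ssp245"`,
#'   `"ssp370"`, `"ssp585"`. For `"historical"` all targets equal the
#'   baselines.
#' @param sigma_frac AR(1) interannual noise standard deviation as a
#'   fraction of the regional baseline (default 0.03).
#' @param rho Lag-1 autocorrelation of the noise, in [0, 1) (default 0.5).
#' @param anomaly_frac Amplitude of the seeded stationary spatial
#'   anomaly, as a fraction of the regional baseline (default 0.05). The
#'   anomaly is demeaned within each region so regional composites are
#'   unaffected.
#' @param table Optional replacement for the default regional
#'   baseline/target table: `data.frame` with columns `variable`,
#'   `region`, `baseline`, `target`, `kind`
#'   (`"integral"`/`"average"`/`"concentration"`), `shape`
#'   (`"uniform"`/`"surface_exp"`).
#' @return An object of class `scenario_spec`.
#' @examples
#' sp <- scenario_spec("ssp585")
#' subset(sp$table, variable == "DOC" & region == "SO")
#' @export
scenario_spec <- function(scenario = c("historical", "ssp126", "ssp245",
                                       "ssp370", "ssp585"),
                          sigma_frac = 0.03, rho = 0.5,
                          anomaly_frac = 0.05, table = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(sigma_frac >= 0, rho >= 0, rho < 1, anomaly_frac >= 0)
  if (is.null(table)) {
    fix <- load_fixture("table1")
    v <- fix$values
    bands <- c("NH", "NI", "LL", "SI", "SO")
    pick <- function(var, scen)
      v$mean[v$variable == var & v$scenario == scen][match(bands, v$region[v$variable == var & v$scenario == scen])]
    tgt_scen <- if (scenario == "historical") "baseline" else scenario
    tab <- rbind(
      data.frame(variable = "T", region = bands,
                 baseline = pick("T", "baseline"), target = pick("T", tgt_scen),
                 kind = "average", shape = "uniform", units = "degC"),
      data.frame(variable = "DOC", region = bands,
                 baseline = pick("DOC", "baseline"), target = pick("DOC", tgt_scen),
                 kind = "integral", shape = "surface_exp", units = "mmol C m-3"),
      data.frame(variable = "POC", region = bands,
                 baseline = pick("POC", "baseline"), target = pick("POC", tgt_scen),
                 kind = "integral", shape = "surface_exp", units = "mmol C m-3"),
      data.frame(variable = "DO", region = bands,
                 baseline = 250, target = 250,
                 kind = "concentration", shape = "uniform", units = "mmol O2 m-3"),
      # trend-free grazer/phytoplankton fields, low-latitude minima
      data.frame(variable = "Z", region = bands,
                 baseline = c(0.7, 0.5, 0.25, 0.5, 0.8),
                 target = c(0.7, 0.5, 0.25, 0.5, 0.8),
                 kind = "concentration", shape = "surface_exp", units = "mmol C m-3"),
      data.frame(variable = "P", region = bands,
                 baseline = c(1.5, 1.0, 0.4, 1.0, 1.8),
                 target = c(1.5, 1.0, 0.4, 1.0, 1.8),
                 kind = "concentration", shape = "surface_exp", units = "mmol C m-3"))
  } else tab <- table
  stopifnot(all(c("variable", "region", "baseline", "target", "kind", "shape")
                %in% names(tab)))
  if (any(tab$baseline < 0 & tab$kind != "average") ||
      any(tab$target < 0 & tab$kind != "average"))
    stop("stock baselines/targets must be non-negative", call. = FALSE)
  structure(list(scenario = scenario, table = tab,
                 sigma_frac = sigma_frac, rho = rho,
                 anomaly_frac = anomaly_frac,
                 ramp_start = 2015, ramp_mid = 2087.5,
                 shape_scale = 150),
            class = "scenario_spec")
}

# Trend ramp: 0 before ramp_start, then linear, normalised so the mean
# over 2076-2099 (midpoint ramp_mid) is exactly 1.
scenario_ramp <- function(years, spec) {
  pmax(0, years - spec$ramp_start) / (spec$ramp_mid - spec$ramp_start)
}

# Vertical profile shape evaluated at depth-level centres.
vertical_shape <- function(name, z, scale = 150) {
  switch(name,
         uniform = rep(1, length(z)),
         surface_exp = exp(-z / scale),
         stop("unknown vertical shape: ", name, call. = FALSE))
}

#' Generate synthetic gridded scenario forcing fields
#'
#' Builds the full `year x depth x lat x lon` fields of a
#' [scenario_spec()]: regional baseline x vertical shape, plus a seeded
#' regionally-demeaned spatial anomaly, plus the scenario trend, plus
#' AR(1) interannual noise, all clipped at zero for stocks (clip count
#' reported as an attribute). Identical seed and spec give bit-identical
#' output.
#'
#' @param spec A [scenario_spec()].
#' @param grid A [build_grid()] grid.
#' @param years Integer vector of years (default 1990:2099).
#' @param seed Integer seed.
#' @return An object of class `field_set`: list with `grid`, `years`,
#'   `scenario`, `vars` (named list of arrays `year x depth x lat x
#'   lon`), `units`; attribute `clipped` counts negativity clips.
#' @examples
#' g <- build_grid(6, 8)
#' fs <- generate_fields(scenario_spec("historical", sigma_frac = 0),
#'                       g, years = 2000:2002, seed = 1)
#' dim(fs$vars$DOC)
#' @export
generate_fields <- function(spec, grid, years = 1990:2099, seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(grid, "bact_grid"))
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  nz <- length(grid$z_centers); ny <- length(years)
  ramp <- scenario_ramp(years, spec)
  cell_region <- matrix(grid$region, nlat, nlon)
  vars <- list(); units <- character(); clipped <- 0L
  with_seed(seed, {
    for (v in unique(spec$table$variable)) {
      tv <- spec$table[spec$table$variable == v, ]
      shape <- vertical_shape(tv$shape[1], grid$z_centers, spec$shape_scale)
      # per-m^2 stocks -> surface concentration via shape-weighted thickness
      conv <- switch(tv$kind[1],
                     integral = depth_reduce(shape, grid$z_centers,
                                             "integrate", c(0, 107)),
                     average = 1, concentration = 1)
      surf0 <- surf1 <- sig <- matrix(0, nlat, nlon)
      for (k in seq_len(nrow(tv))) {
        sel <- cell_region == tv$region[k]
        surf0[sel] <- tv$baseline[k] / conv
        surf1[sel] <- tv$target[k] / conv
        sig[sel] <- spec$sigma_frac * abs(tv$baseline[k]) / conv
      }
      # seeded smooth anomaly, area-demeaned within each region
      ph <- stats::runif(2, 0, 2 * pi)
      sp2 <- outer(sin(2 * pi * (grid$lat + 90) / 180 * 2 + ph[1]),
                   sin(2 * pi * grid$lon / 360 * 2 + ph[2]))
      for (r in levels(grid$region)) {
        sel <- cell_region == r & grid$ocean
        if (any(sel)) {
          w <- grid$weights[sel] / sum(grid$weights[sel])
          sp2[sel] <- sp2[sel] - sum(w * sp2[sel])
        }
      }
      anom <- spec$anomaly_frac * abs(surf0) * sp2
      # AR(1) noise on the surface amplitude, stationary sd = sig
      eps <- array(stats::rnorm(ny * nlat * nlon), c(ny, nlat, nlon))
      noise <- array(0, c(ny, nlat, nlon))
      noise[1, , ] <- sig * eps[1, , ]
      if (ny > 1) for (t in 2:ny)
        noise[t, , ] <- spec$rho * noise[t - 1, , ] +
          sqrt(1 - spec$rho^2) * sig * eps[t, , ]
      arr <- array(NA_real_, c(ny, nz, nlat, nlon))
      for (t in seq_len(ny)) {
        surf <- surf0 + ramp[t] * (surf1 - surf0) + anom + noise[t, , ]
        for (iz in seq_len(nz)) arr[t, iz, , ] <- shape[iz] * surf
      }
      if (tv$kind[1] != "average") { # stocks cannot be negative
        neg <- arr < 0
        if (any(neg)) { clipped <- clipped + sum(neg); arr[neg] <- 0 }
      }
      vars[[v]] <- arr
      units[v] <- if ("units" %in% names(tv)) tv$units[1] else "unknown"
    }
  })
  if (clipped > 0)
    message("generate_fields: clipped ", clipped, " negative stock value(s)")
  structure(list(grid = grid, years = years, scenario = spec$scenario,
                 vars = vars, units = units),
            class = "field_set", clipped = clipped)
}

#' @export
print.field_set <- function(x, ...) {
  cat(sprintf("field_set '%s': %d year(s) %d-%d, vars: %s\n",
              x$scenario, length(x$years), min(x$years), max(x$years),
              paste(names(x$vars), collapse = ", ")))
  invisible(x)
}

#' Generate synthetic station time-series observations
#'
#' Emulates ocean time-series station records (monthly, gappy, lognormal
#' error): the gridded truth at each station's nearest cell and depth
#' level is modulated by a seeded sub-annual harmonic (zero annual mean),
#' multiplied by lognormal measurement error, converted from model units
#' to measurement units (cells L^-1 via the carbon conversion factor, or
#' pmol thymidine L^-1 h^-1 via the thymidine factor), and thinned by
#' seeded missingness.
#'
#' @param truth A `field_set` containing variable `B` (for
#'   `quantity = "abundance"`) or `BP` (for `"thymidine"`).
#' @param stations `data.frame` with columns `station`, `lat`, `lon` and
#'   optionally `depth_m` (default: shallowest level).
#' @param quantity `"abundance"` (cells L^-1) or `"thymidine"`
#'   (pmol L^-1 h^-1).
#' @param sigma_ln Lognormal error standard deviation (of log values).
#' @param missing_frac Fraction of records dropped at random, in [0, 1).
#' @param harm_amp Relative amplitude of the seasonal harmonic.
#' @param constants [conversion_constants()].
#' @param seed Integer seed.
#' @return `data.frame` of records: `station`, `year`, `month`, `date`,
#'   `depth_m`, `quantity`, `value`.
#' @export
generate_station_obs <- function(truth, stations,
                                 quantity = c("abundance", "thymidine"),
                                 sigma_ln = 0.3, missing_frac = 0.1,
                                 harm_amp = 0.2,
                                 constants = conversion_constants(),
                                 seed = 1) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(truth, "field_set"), sigma_ln >= 0,
            missing_frac >= 0, missing_frac < 1, harm_amp >= 0)
  var <- if (quantity == "abundance") "B" else "BP"
  if (is.null(truth$vars[[var]]))
    stop("truth field_set lacks variable ", var, call. = FALSE)
  g <- truth$grid
  if (any(stations$lat < min(g$lat) - 90 / length(g$lat) |
          stations$lat > max(g$lat) + 90 / length(g$lat)))
    stop("station outside grid", call. = FALSE)
  recs <- list()
  with_seed(seed, {
    for (s in seq_len(nrow(stations))) {
      ilat <- which.min(abs(g$lat - stations$lat[s]))
      ilon <- which.min(abs(g$lon - stations$lon[s] %% 360))
      zs <- if ("depth_m" %in% names(stations)) stations$depth_m[s] else g$z_centers[1]
      iz <- which.min(abs(g$z_centers - zs))
      phase <- stats::runif(1, 0, 12)
      for (t in seq_along(truth$years)) {
        base <- truth$vars[[var]][t, iz, ilat, ilon]
        month <- 1:12
        val <- base * (1 + harm_amp * sin(2 * pi * (month - phase) / 12))
        val <- pmax(val, 0) * exp(sigma_ln * stats::rnorm(12))
        val <- if (quantity == "abundance") {
          val / abundance_to_biomass_factor(constants$CCF)
        } else {
          val / thymidine_to_production_factor(constants$TCF, constants$CCF)
        }
        keep <- stats::runif(12) >= missing_frac
        if (any(keep))
          recs[[length(recs) + 1L]] <- data.frame(
            station = stations$station[s],
            lat = g$lat[ilat], lon = g$lon[ilon],
            year = truth$years[t], month = month[keep],
            date = sprintf("%04d-%02d", truth$years[t], month[keep]),
            depth_m = g$z_centers[iz], quantity = quantity,
            value = val[keep])
      }
    }
  })
  do.call(rbind, recs)
}

#' Generate a synthetic gridded monthly observation climatology
#'
#' Emulates a global gridded biomass climatology (sparse spatial
#' coverage, monthly resolution): the time-mean truth per cell is
#' modulated by a seeded seasonal harmonic, multiplied by lognormal
#' error, converted to abundance, and retained per cell-month with
#' probability `coverage`.
#'
#' @inheritParams generate_station_obs
#' @param coverage Probability a cell-month is retained, in (0, 1].
#' @return `data.frame`: `station` (cell id), `lat`, `lon`, `month`,
#'   `depth_m`, `quantity`, `value`.
#' @export
generate_gridded_obs <- function(truth, coverage = 0.1, sigma_ln = 0.3,
                                 harm_amp = 0.2,
                                 constants = conversion_constants(ccf = 9.1),
                                 seed = 1) {
  stopifnot(inherits(truth, "field_set"), coverage > 0, coverage <= 1,
            sigma_ln >= 0)
  if (is.null(truth$vars$B))
    stop("truth field_set lacks variable B", call. = FALSE)
  g <- truth$grid
  nlat <- length(g$lat); nlon <- length(g$lon)
  clim <- apply(truth$vars$B[, 1, , , drop = FALSE], c(3, 4), mean)
  recs <- with_seed(seed, {
    phase <- stats::runif(1, 0, 12)
    out <- list()
    for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
      if (!g$ocean[i, j]) next
      month <- 1:12
      keep <- stats::runif(12) < coverage
      err <- exp(sigma_ln * stats::rnorm(12))
      if (!any(keep)) next
      val <- clim[i, j] *
        (1 + harm_amp * sin(2 * pi * (month - phase) / 12))
      val <- pmax(val, 0) * err /
        abundance_to_biomass_factor(constants$CCF)
      out[[length(out) + 1L]] <- data.frame(
        station = sprintf("cell_%02d_%02d", i, j),
        lat = g$lat[i], lon = g$lon[j], month = month[keep],
        depth_m = g$z_centers[1], quantity = "abundance",
        value = val[keep])
    }
    out
  })
  do.call(rbind, recs)
}
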