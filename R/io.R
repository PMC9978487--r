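#' Write a `field_set` to a self-describing text file
#'
#' CF-flavoured plain-text serialisation (no NetCDF library is assumed):
#' line 1 is a JSON header carrying the coordinate vectors (years, depth
#' interfaces, lat/lon centres), per-variable units, the ocean mask and
#' the scenario id; the body is a long-format CSV
#' (`variable,year,depth,lat,lon,value`) with values printed at full
#' double precision, so a write-read round trip is lossless. Masked or
#' missing cells are stored as `NA`.
#'
#' @param fs A `field_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_fields()]
#' @export
write_fields <- function(fs, path) {
  stopifnot(inherits(fs, "field_set"))
  g <- fs$grid
  units <- fs$units
  missing_units <- setdiff(names(fs$vars), names(units))
  if (length(missing_units)) {
    warning("missing units for: ", paste(missing_units, collapse = ", "),
            "; recorded as 'unknown'", call. = FALSE)
    units[missing_units] <- "unknown"
  }
  hdr <- jsonlite::toJSON(list(
    format = "bactclim_fields", version = 1L, scenario = fs$scenario,
    years = fs$years, z_interfaces = g$z_interfaces,
    lat = g$lat, lon = g$lon, ocean = as.vector(g$ocean),
    units = as.list(units[names(fs$vars)])),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  writeLines("variable,year,depth,lat,lon,value", con)
  nz <- length(g$z_centers)
  idx <- expand.grid(year = fs$years, depth = g$z_centers,
                     lat = g$lat, lon = g$lon)
  for (v in names(fs$vars)) {
    val <- as.vector(fs$vars[[v]])
    writeLines(sprintf("%s,%s,%s,%s,%s,%s", v,
                       format(idx$year), format(idx$depth),
                       format(idx$lat), format(idx$lon),
                       ifelse(is.na(val), "NA", sprintf("%.17g", val))), con)
  }
  invisible(path)
}

#' Read a `field_set` written by [write_fields()]
#'
#' @param path File path.
#' @return A `field_set`; values, coordinates, units and the scenario
#'   attribute round-trip exactly.
#' @export
read_fields <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#"))
    stop("not a bactclim fields file (missing JSON header)", call. = FALSE)
  hdr <- jsonlite::fromJSON(sub("^#", "", first))
  for (co in c("years", "z_interfaces", "lat", "lon"))
    if (is.null(hdr[[co]]))
      stop("missing coordinate in header: ", co, call. = FALSE)
  body <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
  nlat <- length(hdr$lat); nlon <- length(hdr$lon)
  nz <- length(hdr$z_interfaces) - 1; ny <- length(hdr$years)
  mask <- matrix(hdr$ocean, nlat, nlon)
  grid <- build_grid(nlat, nlon, hdr$z_interfaces, ocean_mask = mask)
  vars <- list()
  for (v in unique(body$variable)) {
    d <- body[body$variable == v, ]
    if (nrow(d) != ny * nz * nlat * nlon)
      stop("incomplete field for variable ", v, call. = FALSE)
    vars[[v]] <- array(d$value, c(ny, nz, nlat, nlon))
  }
  units <- unlist(hdr$units)
  if (is.null(units)) units <- setNames(rep("unknown", length(vars)), names(vars))
  structure(list(grid = grid, years = hdr$years, scenario = hdr$scenario,
                 vars = vars, units = units),
            class = "field_set")
}

#' Write / read observation records as CSV
#'
#' Thin wrappers fixing the record schema (`station`, `date`/`month`,
#' `depth_m`, `quantity`, `value`, plus `lat`/`lon` where present).
#'
#' @param obs Records from [generate_station_obs()] or
#'   [generate_gridded_obs()].
#' @param path File path.
#' @return `path` (write) or the records `data.frame` (read).
#' @export
write_obs <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_obs
#' @export
read_obs <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
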