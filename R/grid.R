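#' Build a lat-lon-depth analysis grid
#'
#' Regular latitude/longitude grid with cosine-latitude area weights
#' (normalised to sum to 1 over ocean cells) and a vertical level
#' structure given by interface depths. The default vertical grid has 10
#' levels spanning 0-250 m with 6 level centres inside the upper-ocean
#' analysis layer (0-107 m).
#'
#' @param n_lat Number of latitude rows (>= 6 so every latitudinal band
#'   is populated; centres span -90..90 at equal spacing).
#' @param n_lon Number of longitude columns (centres span 0..360).
#' @param z_interfaces Strictly increasing depth interfaces (m), from the
#'   surface (0) to at least 107 m.
#' @param ocean_mask Logical `n_lat x n_lon` matrix, `TRUE` for ocean
#'   cells; default all-ocean.
#' @return An object of class `bact_grid`: list with `lat`, `lon`,
#'   `z_interfaces`, `z_centers`, `weights` (`n_lat x n_lon`, zero on
#'   land, sums to 1), `ocean` mask, and `region` (`n_lat`-length factor
#'   of latitudinal bands, see [regionalize()]).
#' @examples
#' g <- build_grid(18, 36)
#' sum(g$weights) # 1
#' @export
build_grid <- function(n_lat = 18, n_lon = 36,
                       z_interfaces = c(0, 10, 25, 45, 65, 85, 107,
                                        130, 160, 200, 250),
                       ocean_mask = NULL) {
  if (n_lat < 6) stop("n_lat must be >= 6", call. = FALSE)
  if (is.unsorted(z_interfaces, strictly = TRUE))
    stop("depth interfaces must be strictly increasing", call. = FALSE)
  if (max(z_interfaces) < 107)
    stop("depth interfaces must span at least 107 m", call. = FALSE)
  lat <- seq(-90 + 90 / n_lat, 90 - 90 / n_lat, length.out = n_lat)
  lon <- seq(360 / n_lon / 2, 360 - 360 / n_lon / 2, length.out = n_lon)
  z_centers <- (head2(z_interfaces) + z_interfaces[-1]) / 2
  if (sum(z_centers <= 107) < 2)
    stop("need at least 2 level centres in the 0-107 m layer", call. = FALSE)
  if (is.null(ocean_mask)) ocean_mask <- matrix(TRUE, n_lat, n_lon)
  stopifnot(is.logical(ocean_mask), all(dim(ocean_mask) == c(n_lat, n_lon)))
  w <- matrix(cos(lat * pi / 180), n_lat, n_lon)
  w[!ocean_mask] <- 0
  if (sum(w) <= 0) stop("ocean mask leaves no ocean cells", call. = FALSE)
  w <- w / sum(w)
  region <- regionalize(lat)
  tab <- table(region[rep(seq_len(n_lat), n_lon)][as.vector(ocean_mask)])
  if (any(tab == 0))
    stop("latitudinal band(s) with zero ocean cells: ",
         paste(names(tab)[tab == 0], collapse = ", "), call. = FALSE)
  structure(list(lat = lat, lon = lon,
                 z_interfaces = z_interfaces, z_centers = z_centers,
                 weights = w, ocean = ocean_mask, region = region),
            class = "bact_grid")
}

head2 <- function(x) x[-length(x)]

#' @export
print.bact_grid <- function(x, ...) {
  cat(sprintf("bact_grid: %d lat x %d lon, %d depth levels (%g-%g m), %d ocean cells\n",
              length(x$lat), length(x$lon), length(x$z_centers),
              min(x$z_interfaces), max(x$z_interfaces), sum(x$ocean)))
  invisible(x)
}

#' Assign latitudes to the standard latitudinal bands
#'
#' Bands: `NH` northern high latitudes (lat >= 50), `NI` northern
#' intermediates (30 <= lat < 50), `LL` low latitudes (-30 <= lat < 30),
#' `SI` southern intermediates (-50 <= lat < -30), `SO` Southern Ocean
#' (lat < -50). Boundaries are half-open and poleward-inclusive at
#' +/-50 degrees, so every latitude falls in exactly one band.
#'
#' @param lat Numeric vector of latitudes (degrees north).
#' @return Factor with levels `NH`, `NI`, `LL`, `SI`, `SO`.
#' @examples
#' regionalize(c(60, 0, -60))
#' @export
regionalize <- function(lat) {
  stopifnot(is.numeric(lat), all(abs(lat) <= 90))
  r <- cut(lat, breaks = c(-90.001, -50, -30, 30, 50, 90.001),
           labels = c("SO", "SI", "LL", "NI", "NH"), right = FALSE)
  factor(r, levels = c("NH", "NI", "LL", "SI", "SO"))
}
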