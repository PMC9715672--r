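# Regular lat-lon grids with spherical-band cell areas.

EARTH_RADIUS_M <- 6371e3

#' Define a regular latitude-longitude analysis grid
#'
#' Builds a regular lattice of cell centers covering the requested window and
#' computes the area of every cell from the spherical band formula
#' \eqn{A = R^2 \, \Delta\lambda \, (\sin\phi_2 - \sin\phi_1)} with
#' \eqn{R = 6371} km, converted to hectares. The default window is an EU-like
#' domain (35.25-69.25 deg N, 9.25 deg W - 34.25 deg E) at 0.5 degree
#' resolution, roughly 50 km x 50 km cells in mid latitudes.
#'
#' @param lat_min,lat_max,lon_min,lon_max Domain bounds in decimal degrees.
#' @param resolution Cell size in degrees; must divide both extents.
#' @return An object of class `halven_grid`: a list with cell-center vectors
#'   `lat` and `lon`, `resolution`, the per-cell area matrix `cell_area_ha`
#'   (rows = latitude bands, columns = longitudes) and the dimensions
#'   `nlat`, `nlon`.
#' @examples
#' g <- generate_grid(44.75, 45.75, 5.75, 6.75, resolution = 0.5)
#' dim(g$cell_area_ha)
#' @export
generate_grid <- function(lat_min = 35.25, lat_max = 69.25,
                          lon_min = -9.25, lon_max = 34.25,
                          resolution = 0.5) {
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number")
  if (lat_min >= lat_max)
    stop("`lat_min` must be strictly smaller than `lat_max`")
  if (lon_min >= lon_max)
    stop("`lon_min` must be strictly smaller than `lon_max`")
  if (lat_min < -90 || lat_max > 90)
    stop("latitude bounds must lie in [-90, 90]")
  nlat <- (lat_max - lat_min) / resolution
  nlon <- (lon_max - lon_min) / resolution
  if (abs(nlat - round(nlat)) > 1e-8 || abs(nlon - round(nlon)) > 1e-8)
    stop("`resolution` must divide both the latitude and longitude extents")
  nlat <- as.integer(round(nlat))
  nlon <- as.integer(round(nlon))

  lat <- lat_min + (seq_len(nlat) - 0.5) * resolution
  lon <- lon_min + (seq_len(nlon) - 0.5) * resolution

  band_area <- band_area_ha(lat - resolution / 2, lat + resolution / 2,
                            resolution)
  cell_area_ha <- matrix(band_area, nrow = nlat, ncol = nlon)
  dimnames(cell_area_ha) <- list(format(lat), format(lon))

  structure(
    list(lat = lat, lon = lon, resolution = resolution,
         cell_area_ha = cell_area_ha, nlat = nlat, nlon = nlon),
    class = "halven_grid"
  )
}

# Area in hectares of one resolution-wide cell in the band [phi1, phi2].
band_area_ha <- function(phi1_deg, phi2_deg, dlambda_deg) {
  phi1 <- phi1_deg * pi / 180
  phi2 <- phi2_deg * pi / 180
  dlambda <- dlambda_deg * pi / 180
  area_m2 <- EARTH_RADIUS_M^2 * dlambda * (sin(phi2) - sin(phi1))
  area_m2 / 1e4
}

#' @export
print.halven_grid <- function(x, ...) {
  cat(sprintf("<halven_grid> %d x %d cells at %.3g deg\n",
              x$nlat, x$nlon, x$resolution))
  cat(sprintf("  lat %.2f..%.2f, lon %.2f..%.2f (cell centers)\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  cat(sprintf("  total area %.4g Mha\n", sum(x$cell_area_ha) / 1e6))
  invisible(x)
}

# Shared sanity check used by layer constructors.
stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop("maps are not defined on the same grid")
  invisible(TRUE)
}
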