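# Spherical geodesy on a sphere of radius 6371 km. At subpolar latitudes the
# error relative to an ellipsoid is below 0.5%, which is far inside the noise
# of Argos positioning, so no projection machinery is used anywhere.

EARTH_RADIUS_KM <- 6371

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Great-circle distance between points
#'
#' Haversine distance on a spherical Earth (radius 6371 km). Inputs are
#' vectorized and recycled.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84 lon/lat).
#' @return Distance(s) in kilometres.
#' @export
gc_distance_km <- function(lon1, lat1, lon2, lat2) {
  phi1 <- deg2rad(lat1); phi2 <- deg2rad(lat2)
  dphi <- phi2 - phi1
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' Forward azimuth from the first point toward the second, in degrees true
#' on [0, 360). Coincident points return 0 by convention.
#'
#' @inheritParams gc_distance_km
#' @return Bearing(s) in degrees.
#' @export
gc_bearing_deg <- function(lon1, lat1, lon2, lat2) {
  phi1 <- deg2rad(lat1); phi2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  b <- rad2deg(atan2(y, x)) %% 360
  b[lon1 == lon2 & lat1 == lat2] <- 0
  b
}

#' Destination point along a great circle
#'
#' @inheritParams gc_distance_km
#' @param lon,lat Start coordinates, degrees.
#' @param bearing_deg Initial bearing, degrees true.
#' @param dist_km Distance travelled, km.
#' @return A list with components `lon` and `lat` (degrees, lon in
#'   (-180, 180]).
#' @export
gc_destination <- function(lon, lat, bearing_deg, dist_km) {
  delta <- dist_km / EARTH_RADIUS_KM
  theta <- deg2rad(bearing_deg)
  phi1 <- deg2rad(lat)
  lam1 <- deg2rad(lon)
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(
    sin(theta) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  lon2 <- rad2deg(lam2)
  lon2 <- ((lon2 + 180) %% 360) - 180
  lon2[lon2 == -180] <- 180
  list(lon = lon2, lat = rad2deg(phi2))
}

# Normalize longitudes to (-180, 180].
normalize_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}
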