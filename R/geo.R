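# Geographic helpers shared across modules. Longitudes are normalized to
# [0, 360) once at ingest (the study sector spans 0-55E, so no wrap seam);
# latitudes in decimal degrees, south negative.

EARTH_RADIUS_M <- 6371000
DEG2RAD <- pi / 180

#' Normalize longitudes to [0, 360)
#' @param lon longitudes, decimal degrees.
#' @return longitudes wrapped into [0, 360).
#' @export
normalize_lon <- function(lon) ((lon %% 360) + 360) %% 360

# great-circle distance matrix in km between two sets of points (lon/lat
# degrees), haversine on a 6371 km sphere (geosphere's haversine defaults to
# the WGS84 equatorial radius, which would be inconsistent with the fixed
# Earth radius used for velocity conversions)
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  la1 <- lat1 * DEG2RAD; la2 <- lat2 * DEG2RAD
  lo1 <- lon1 * DEG2RAD; lo2 <- lon2 * DEG2RAD
  dphi <- outer(la1, la2, `-`)
  dlam <- outer(lo1, lo2, `-`)
  a <- sin(dphi / 2)^2 + outer(cos(la1), cos(la2)) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * asin(sqrt(a)) * EARTH_RADIUS_M / 1000
}

# central angle in degrees between points and a single center
angular_dist_deg <- function(lon, lat, lon0, lat0) {
  gc_dist_km(lon, lat, lon0, lat0)[, 1] * 1000 / EARTH_RADIUS_M / DEG2RAD
}

# meters of east/north displacement per degree of lon/lat at a latitude
m_per_deg_lon <- function(lat) EARTH_RADIUS_M * DEG2RAD * cos(lat * DEG2RAD)
m_per_deg_lat <- function(lat) EARTH_RADIUS_M * DEG2RAD + 0 * lat
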