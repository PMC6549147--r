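# Hydrothermal tracer sections: grid station profiles of the helium-isotope
# anomaly into a depth x along-track section, and flag stations sitting in
# energetic (high-EKE) surface environments.

#' Grid tracer stations into a vertical section
#'
#' Linear interpolation only (no overshoot on sparse tracer data): each
#' station profile is interpolated to the depth grid, then the section is
#' filled by linear interpolation in cumulative great-circle along-track
#' distance between stations. Cells below a station's deepest sample, or
#' beyond the end stations, stay missing.
#'
#' @param stations ordered list of stations (see [read_tracer_stations()]).
#' @param depth_grid target depths, m (default 0-3500 every 100).
#' @param n_along number of along-track nodes (default 50).
#' @return a \code{vb_tracer_section}: \code{along_km}, \code{depth},
#'   \code{field} (along x depth, percent), \code{station_along_km},
#'   \code{station_lat}, \code{station_lon}.
#' @export
grid_section <- function(stations, depth_grid = seq(0, 3500, by = 100),
                         n_along = 50) {
  ns <- length(stations)
  if (ns < 1) stop("at least one station is required")
  if (ns == 1) warning("single station: returning a one-column section")
  lon <- vapply(stations, `[[`, numeric(1), "lon")
  lat <- vapply(stations, `[[`, numeric(1), "lat")
  seg <- if (ns > 1)
    vapply(seq_len(ns - 1), function(i)
      gc_dist_km(lon[i], lat[i], lon[i + 1], lat[i + 1])[1, 1], numeric(1))
  else numeric(0)
  along <- c(0, cumsum(seg))
  prof <- vapply(stations, function(s) {
    ok <- is.finite(s$delta3he)
    out <- rep(NA_real_, length(depth_grid))
    if (sum(ok) >= 2) {
      inr <- depth_grid >= min(s$depth[ok]) & depth_grid <= max(s$depth[ok])
      out[inr] <- stats::approx(s$depth[ok], s$delta3he[ok],
                                depth_grid[inr])$y
    }
    out
  }, numeric(length(depth_grid)))          # depth x station
  xg <- if (ns > 1) seq(0, along[ns], length.out = n_along) else 0
  field <- matrix(NA_real_, length(xg), length(depth_grid))
  for (k in seq_along(depth_grid)) {
    ok <- is.finite(prof[k, ])
    if (sum(ok) >= 2)
      field[, k] <- stats::approx(along[ok], prof[k, ok], xg, rule = 1)$y
    else if (sum(ok) == 1 && ns == 1)
      field[, k] <- prof[k, ok]
  }
  structure(list(along_km = xg, depth = depth_grid, field = field,
                 station_along_km = along, station_lat = lat,
                 station_lon = lon),
            class = "vb_tracer_section")
}

#' @export
print.vb_tracer_section <- function(x, ...) {
  cat(sprintf("<vb_tracer_section %d stations, %.0f km track, %d x %d grid, max %.2f%%>\n",
              length(x$station_along_km), max(x$along_km), length(x$along_km),
              length(x$depth), suppressWarnings(max(x$field, na.rm = TRUE))))
  invisible(x)
}

#' Flag stations in high surface-EKE environments
#'
#' A station is flagged when the surface EKE at the nearest fine-grid node
#' strictly exceeds the threshold (default 150 cm^2 s^-2). Stations outside
#' the EKE field stay unflagged with a warning.
#'
#' @param stations list of stations.
#' @param eke_field a \code{vb_grid} of EKE, cm^2 s^-2.
#' @param threshold cm^2 s^-2 (default 150).
#' @return logical vector, one per station.
#' @export
flag_high_eke <- function(stations, eke_field, threshold = 150) {
  lon <- normalize_lon(vapply(stations, `[[`, numeric(1), "lon"))
  lat <- vapply(stations, `[[`, numeric(1), "lat")
  v <- grid_lookup(eke_field, lon, lat, method = "nearest")
  inside <- lon >= min(eke_field$lon) & lon <= max(eke_field$lon) &
    lat >= min(eke_field$lat) & lat <= max(eke_field$lat)
  if (any(!inside | is.na(v)))
    warning(sum(!inside | is.na(v)), " station(s) outside the EKE field left unflagged")
  out <- !is.na(v) & inside & v > threshold
  out
}
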