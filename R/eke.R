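# Eddy kinetic energy: deep EKE from float park-depth displacements binned in
# 1-degree boxes (EKE = (u'^2 + v'^2)/2 from per-box velocity variances),
# surface EKE from gridded velocity time series, and Gaussian-correlation
# smoothing onto a fine grid.

#' Velocity from a deep displacement record
#'
#' Local-tangent-plane conversion of a displacement between two surfacings:
#' \code{u = dlon * cos(latbar) * (pi/180) * R / dt},
#' \code{v = dlat * (pi/180) * R / dt}, with R = 6371 km and latbar the mean
#' latitude. Records shorter than \code{min_days} are rejected.
#'
#' Each velocity sample is attributed to the cycle's start fix, so that the
#' binning position is statistically independent of the velocity itself
#' (attributing to the displacement midpoint would sort fast parcels into
#' downstream boxes and bias within-box variances low).
#'
#' @param df displacement data.frame (see [read_displacements()]).
#' @param min_days minimum drift duration, days (default 1).
#' @return data.frame \code{lon, lat, u, v} (cm s^-1), positions at the
#'   cycle start; rejected rows dropped with a message.
#' @export
displacement_velocity <- function(df, min_days = 1) {
  dt <- as.numeric(difftime(df$t1, df$t0, units = "secs"))
  keep <- dt >= min_days * 86400
  if (any(!keep))
    message(sum(!keep), " displacement record(s) shorter than ", min_days,
            " day(s) rejected")
  df <- df[keep, , drop = FALSE]; dt <- dt[keep]
  latbar <- (df$lat0 + df$lat1) / 2
  dlon <- df$lon1 - df$lon0
  dlon <- ifelse(dlon > 180, dlon - 360, ifelse(dlon < -180, dlon + 360, dlon))
  u <- dlon * cos(latbar * DEG2RAD) * DEG2RAD * EARTH_RADIUS_M / dt
  v <- (df$lat1 - df$lat0) * DEG2RAD * EARTH_RADIUS_M / dt
  data.frame(lon = normalize_lon(df$lon0),
             lat = df$lat0, u = u * 100, v = v * 100)
}

#' Bin velocities into boxes and form deep EKE
#'
#' Velocity samples are pooled into \code{bin_deg} boxes; per box the mean
#' and population variance of each component give
#' EKE = (var(u) + var(v)) / 2. Boxes with \code{count <= min_count} are
#' masked (strictly more than \code{min_count} samples are required).
#'
#' @param vel data.frame \code{lon, lat, u, v} with velocities in cm s^-1.
#' @param bin_deg box size, degrees (default 1).
#' @param min_count minimum sample count, exclusive (default 5).
#' @return a \code{vb_eke} grid: bin centers \code{lon}, \code{lat} and
#'   matrices \code{mean_u, mean_v, var_u, var_v, count, eke} (cm^2 s^-2;
#'   masked boxes NA).
#' @export
bin_deep_eke <- function(vel, bin_deg = 1, min_count = 5) {
  if (!nrow(vel)) stop("no velocity samples")
  lon <- normalize_lon(vel$lon)
  i <- floor(lon / bin_deg); j <- floor(vel$lat / bin_deg)
  ic <- sort(unique(i)); jc <- sort(unique(j))
  flat <- (match(j, jc) - 1L) * length(ic) + match(i, ic)
  pool <- function(x) {
    m <- matrix(0, length(ic), length(jc))
    s <- rowsum(x, flat)
    m[as.integer(rownames(s))] <- s
    m
  }
  n <- pool(rep(1, nrow(vel)))
  mean_u <- pool(vel$u) / n; mean_v <- pool(vel$v) / n
  var_u <- pmax(pool(vel$u^2) / n - mean_u^2, 0)
  var_v <- pmax(pool(vel$v^2) / n - mean_v^2, 0)
  eke <- (var_u + var_v) / 2
  mask <- n <= min_count
  for (m in c("mean_u", "mean_v", "var_u", "var_v", "eke"))
    assign(m, {x <- get(m); x[mask] <- NA_real_; x})
  structure(list(lon = (ic + 0.5) * bin_deg, lat = (jc + 0.5) * bin_deg,
                 mean_u = mean_u, mean_v = mean_v,
                 var_u = var_u, var_v = var_v,
                 count = n, eke = eke, units = "cm2 s-2"),
            class = "vb_eke")
}

#' @export
print.vb_eke <- function(x, ...) {
  cat(sprintf("<vb_eke %d x %d boxes, %d unmasked, EKE %.1f..%.1f %s>\n",
              length(x$lon), length(x$lat), sum(is.finite(x$eke)),
              suppressWarnings(min(x$eke, na.rm = TRUE)),
              suppressWarnings(max(x$eke, na.rm = TRUE)), x$units))
  invisible(x)
}

#' Smooth a binned EKE field onto a fine grid
#'
#' Gaussian-correlation interpolation weighted by the per-box sample count:
#' the value at a fine node is sum(w_i * eke_i) / sum(w_i) over unmasked
#' boxes, with w_i = count_i * exp(-d_i^2 / (2 radius^2)) and d_i the
#' great-circle distance to box center i. Nodes whose total weight falls
#' below \code{w_floor} are left missing.
#'
#' @param grid a \code{vb_eke}.
#' @param radius_km decorrelation radius, km (default 100).
#' @param fine_res_deg fine grid resolution, degrees (default 0.25).
#' @param w_floor minimum total weight (default 1e-3).
#' @return a \code{vb_grid} of smoothed EKE (cm^2 s^-2).
#' @export
smooth_eke <- function(grid, radius_km = 100, fine_res_deg = 0.25,
                       w_floor = 1e-3) {
  ok <- which(is.finite(grid$eke))
  if (!length(ok)) {
    warning("all boxes masked; smoothed field is empty")
    return(field_grid(grid$lon, grid$lat,
                      matrix(NA_real_, length(grid$lon), length(grid$lat)),
                      "eke_cm2_s2"))
  }
  ctr <- expand.grid(lon = grid$lon, lat = grid$lat, KEEP.OUT.ATTRS = FALSE)
  eke <- as.vector(grid$eke)[ok]
  cnt <- as.vector(grid$count)[ok]
  ctr <- ctr[ok, , drop = FALSE]
  flon <- seq(min(grid$lon), max(grid$lon), by = fine_res_deg)
  flat <- seq(min(grid$lat), max(grid$lat), by = fine_res_deg)
  nodes <- expand.grid(lon = flon, lat = flat, KEEP.OUT.ATTRS = FALSE)
  d <- gc_dist_km(nodes$lon, nodes$lat, ctr$lon, ctr$lat)
  w <- exp(-d^2 / (2 * radius_km^2)) *
    matrix(cnt, nrow(nodes), length(cnt), byrow = TRUE)
  sw <- rowSums(w)
  val <- as.vector(w %*% eke) / sw
  val[sw < w_floor] <- NA_real_
  field_grid(flon, flat, matrix(val, length(flon), length(flat)), "eke_cm2_s2")
}

#' Surface EKE from a gridded velocity time series
#'
#' Per grid node, velocity anomalies are deviations from the node's time
#' mean; EKE is the time mean of (u'^2 + v'^2)/2, reported in cm^2 s^-2.
#'
#' @param series a \code{vb_velocity} (m s^-1).
#' @return a \code{vb_grid} of EKE, cm^2 s^-2 (NA where any input missing).
#' @export
surface_eke <- function(series) {
  nt <- length(series$time)
  if (nt < 2) {
    warning("single time slice: surface EKE is identically zero")
    return(field_grid(series$lon, series$lat,
                      matrix(0, length(series$lon), length(series$lat)),
                      "eke_cm2_s2"))
  }
  mu <- apply(series$u, c(1, 2), mean)
  mv <- apply(series$v, c(1, 2), mean)
  up2 <- apply(sweep(series$u, c(1, 2), mu)^2, c(1, 2), mean)
  vp2 <- apply(sweep(series$v, c(1, 2), mv)^2, c(1, 2), mean)
  field_grid(series$lon, series$lat, (up2 + vp2) / 2 * 1e4, "eke_cm2_s2")
}
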