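# Lagrangian iron delivery: backward particle advection through gridded
# velocities (4th-order Runge-Kutta, 6 h steps, linear space-time
# interpolation), most-recent-contact search against iron-source masks, and
# exponential scavenging of the delivered iron fraction.

#' Interpolate a gridded velocity series in space and time
#'
#' Bilinear in space, linear in time. Missing (land) spatial neighbors get
#' zero weight with the remaining weights renormalized; when all four
#' neighbors are missing the velocity is undefined (NA) and particles there
#' are treated as beached. A single-slice series is constant in time.
#'
#' @param series a \code{vb_velocity}.
#' @param lon,lat query positions, degrees (vectorized).
#' @param t query time, days since 2000-01-01 (scalar).
#' @return list \code{u}, \code{v} in m s^-1.
#' @export
interp_velocity <- function(series, lon, lat, t) {
  nt <- length(series$time)
  if (nt == 1) {
    k0 <- k1 <- 1; wt <- 0
  } else {
    if (t < series$time[1] - 1e-9 || t > series$time[nt] + 1e-9)
      stop(sprintf("time %.3f outside velocity series span [%.3f, %.3f]",
                   t, series$time[1], series$time[nt]))
    k0 <- max(1, min(nt - 1, findInterval(t, series$time)))
    k1 <- k0 + 1
    wt <- (t - series$time[k0]) / (series$time[k1] - series$time[k0])
    wt <- min(max(wt, 0), 1)
  }
  u0 <- bilinear_sample(series$lon, series$lat, series$u[, , k0], lon, lat)
  v0 <- bilinear_sample(series$lon, series$lat, series$v[, , k0], lon, lat)
  if (wt == 0) return(list(u = u0, v = v0))
  u1 <- bilinear_sample(series$lon, series$lat, series$u[, , k1], lon, lat)
  v1 <- bilinear_sample(series$lon, series$lat, series$v[, , k1], lon, lat)
  list(u = (1 - wt) * u0 + wt * u1, v = (1 - wt) * v0 + wt * v1)
}

#' One Runge-Kutta step of particle advection
#'
#' Classical fourth-order step of dx/dt = u, dy/dt = v on the sphere, with
#' degrees-to-meters conversion using cos(lat) at each stage. Backward
#' integration uses a negated time increment. Particles for which any stage
#' velocity is undefined are beached: their position is left unchanged and
#' flagged.
#'
#' @param lon,lat positions, degrees (vectorized).
#' @param t current time, days since 2000-01-01.
#' @param dt_h step, hours (default 6).
#' @param series a \code{vb_velocity}, or a function \code{(lon, lat, t)}
#'   returning \code{list(u, v)} in m s^-1 (analytic flow, no grid error).
#' @param direction \code{"forward"} or \code{"backward"}.
#' @return list \code{lon}, \code{lat}, \code{beached} (logical).
#' @export
rk4_step <- function(lon, lat, t, dt_h = 6, series,
                     direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  h <- dt_h / 24 * if (direction == "backward") -1 else 1
  deriv <- function(lo, la, tt) {
    vv <- if (is.function(series)) series(lo, la, tt)
          else interp_velocity(series, lo, la, tt)
    list(dlon = vv$u * 86400 / m_per_deg_lon(la),
         dlat = vv$v * 86400 / m_per_deg_lat(la))
  }
  k1 <- deriv(lon, lat, t)
  k2 <- deriv(lon + h / 2 * k1$dlon, lat + h / 2 * k1$dlat, t + h / 2)
  k3 <- deriv(lon + h / 2 * k2$dlon, lat + h / 2 * k2$dlat, t + h / 2)
  k4 <- deriv(lon + h * k3$dlon, lat + h * k3$dlat, t + h)
  dlon <- h / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
  dlat <- h / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
  beached <- !is.finite(dlon) | !is.finite(dlat)
  list(lon = ifelse(beached, lon, lon + dlon),
       lat = ifelse(beached, lat, lat + dlat),
       beached = beached)
}

#' Iron-source masks
#'
#' Two source kinds: \code{disk_mask} builds a set of disks (membership by
#' great-circle angular distance to a center within the radius, in degrees);
#' \code{shallow_mask} marks water shallower than \code{max_depth} on a
#' bathymetry grid (nearest-node lookup).
#'
#' @param disks data.frame \code{lon, lat, radius_deg}.
#' @param label mask label reported on contact.
#' @return a \code{vb_source_mask}.
#' @export
disk_mask <- function(disks, label = "ridge_upwelling") {
  stopifnot(all(c("lon", "lat", "radius_deg") %in% names(disks)))
  structure(list(kind = "disk_set", disks = disks, label = label),
            class = "vb_source_mask")
}

#' @rdname disk_mask
#' @param bathy a \code{vb_grid} of depth (m, positive down).
#' @param max_depth shallow cutoff, m (default 500).
#' @export
shallow_mask <- function(bathy, max_depth = 500, label = "shallow_bathymetry") {
  structure(list(kind = "shallow_bathymetry", bathy = bathy,
                 max_depth = max_depth, label = label),
            class = "vb_source_mask")
}

#' Test membership of positions in a source mask
#' @param mask a \code{vb_source_mask}.
#' @param lon,lat positions, degrees.
#' @return logical vector.
#' @export
mask_contains <- function(mask, lon, lat) {
  lon <- normalize_lon(lon)
  if (mask$kind == "disk_set") {
    inside <- rep(FALSE, length(lon))
    for (r in seq_len(nrow(mask$disks)))
      inside <- inside |
        (angular_dist_deg(lon, lat, normalize_lon(mask$disks$lon[r]),
                          mask$disks$lat[r]) <= mask$disks$radius_deg[r])
    inside
  } else {
    d <- grid_lookup(mask$bathy, lon, lat, method = "nearest")
    !is.na(d) & d < mask$max_depth
  }
}

#' Fraction of bioavailable iron surviving scavenging
#'
#' Exponential decay of dissolved iron with water-parcel age since source
#' contact: \code{exp(-age / efold)}.
#'
#' @param age days since source contact (>= 0).
#' @param efold scavenging e-folding time, days.
#' @return fraction between 0 and 1.
#' @export
iron_fraction <- function(age, efold = 90) {
  if (any(!is.na(age) & age < 0)) stop("age must be non-negative")
  if (efold <= 0) stop("efold must be positive")
  exp(-age / efold)
}

# Vectorized backward contact search shared by trace_last_contact() and
# seasonal_delivery_map(). Integration is truncated at the start of the
# velocity record when the lookback horizon extends past it.
backward_contacts <- function(lon, lat, t_seed, series, masks,
                              lookback_days = 150, dt_h = 6,
                              record_path = FALSE) {
  n <- length(lon)
  tmin <- if (!is.function(series) && length(series$time) > 1)
    series$time[1] else -Inf
  nstep <- floor(min(lookback_days * 24 / dt_h,
                     if (is.finite(tmin)) (t_seed - tmin) * 24 / dt_h else Inf))
  age <- rep(NA_real_, n)
  label <- rep(NA_character_, n)
  beached <- rep(FALSE, n)
  path <- if (record_path) list(data.frame(time = t_seed, lon = lon, lat = lat))
          else NULL
  t <- t_seed
  active <- rep(TRUE, n)
  check <- function(active, t) {
    for (m in masks) {
      hit <- active & mask_contains(m, lon, lat)
      hit[!is.na(label)] <- FALSE
      age[hit] <<- t_seed - t
      label[hit] <<- m$label
      active[hit] <- FALSE
    }
    active
  }
  active <- check(active, t)
  step <- 0
  while (any(active) && step < nstep) {
    st <- rk4_step(lon[active], lat[active], t, dt_h, series, "backward")
    newly_beached <- which(active)[st$beached]
    lon[active] <- st$lon; lat[active] <- st$lat
    beached[newly_beached] <- TRUE
    active[newly_beached] <- FALSE
    t <- t - dt_h / 24
    step <- step + 1
    if (record_path)
      path[[length(path) + 1]] <- data.frame(time = t, lon = lon, lat = lat)
    active <- check(active, t)
  }
  list(age = age, label = label, beached = beached,
       end_lon = lon, end_lat = lat,
       path = if (record_path) do.call(rbind, rev(path)) else NULL)
}

#' Trace a particle backward to its most recent iron-source contact
#'
#' Integrates one particle backward in time from its seed position for up to
#' \code{lookback_days}; the first source contact encountered backward in
#' time is the particle's most recent contact. The contact age converts to a
#' delivered-iron fraction by [iron_fraction()].
#'
#' @param seed_lon,seed_lat seed position, degrees.
#' @param t_seed seed time, days since 2000-01-01 (or POSIXct/Date).
#' @param series a \code{vb_velocity}.
#' @param masks list of \code{vb_source_mask}, in precedence order.
#' @param lookback_days backward horizon, days (default 150).
#' @param dt_h step, hours (default 6).
#' @param efold scavenging e-folding time, days (default 90).
#' @return a \code{vb_trajectory}: \code{seed_lon, seed_lat, t_seed,
#'   contact_time, age, iron_fraction, source_label, beached, path}
#'   (data.frame time/lon/lat in time-increasing order).
#' @export
trace_last_contact <- function(seed_lon, seed_lat, t_seed, series, masks,
                               lookback_days = 150, dt_h = 6, efold = 90) {
  if (!is.numeric(t_seed)) t_seed <- days_since_2000(t_seed)
  r <- backward_contacts(seed_lon, seed_lat, t_seed, series, masks,
                         lookback_days, dt_h, record_path = TRUE)
  structure(list(seed_lon = seed_lon, seed_lat = seed_lat, t_seed = t_seed,
                 contact_time = if (is.na(r$age[1])) NA_real_ else t_seed - r$age[1],
                 age = r$age[1],
                 iron_fraction = if (is.na(r$age[1])) NA_real_
                                 else iron_fraction(r$age[1], efold),
                 source_label = r$label[1], beached = r$beached[1],
                 path = r$path),
            class = "vb_trajectory")
}

#' @export
print.vb_trajectory <- function(x, ...) {
  cat(sprintf("<vb_trajectory seed (%.3f, %.3f)  %s>\n", x$seed_lon, x$seed_lat,
              if (is.na(x$age)) "no source contact within lookback"
              else sprintf("contact '%s' %.2f d ago, iron fraction %.3f",
                           x$source_label, x$age, x$iron_fraction)))
  invisible(x)
}

#' Climatological iron-delivery map
#'
#' Seeds every node of a regular grid, repeatedly through each bloom season
#' (every \code{seed_every_days}), traces each seed backward to its most
#' recent source contact, and averages contact age and delivered-iron
#' percentage across seed times and seasons. Node-seasons without contact
#' are excluded from the means; contact counts are recorded.
#'
#' @param series_by_season list of \code{vb_velocity}, one per season.
#' @param seed_lon,seed_lat seed-grid coordinate vectors, degrees.
#' @param masks list of \code{vb_source_mask}.
#' @param efold scavenging e-folding time, days.
#' @param lookback_days backward horizon, days.
#' @param dt_h step, hours.
#' @param seed_every_days seed-time cadence within a season (default 10).
#' @return a \code{vb_delivery}: \code{lon}, \code{lat}, matrices
#'   \code{mean_age} (days), \code{mean_delivery} (percent, 0 to 100),
#'   \code{n_contact}, \code{n_seeded}.
#' @export
seasonal_delivery_map <- function(series_by_season, seed_lon, seed_lat, masks,
                                  efold = 90, lookback_days = 150, dt_h = 6,
                                  seed_every_days = 10) {
  if (!length(series_by_season)) stop("at least one season is required")
  if (!length(masks)) {
    warning("no source masks: delivery map is all-missing")
  }
  nodes <- expand.grid(lon = seed_lon, lat = seed_lat, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(nodes)
  sum_age <- sum_frac <- n_contact <- n_seeded <- rep(0, n)
  for (series in series_by_season) {
    tspan <- range(series$time)
    t_seeds <- seq(min(tspan[1] + lookback_days, tspan[2]), tspan[2],
                   by = seed_every_days)
    if (!length(t_seeds)) t_seeds <- tspan[2]
    for (ts in t_seeds) {
      r <- if (length(masks))
        backward_contacts(nodes$lon, nodes$lat, ts, series, masks,
                          lookback_days, dt_h)
      else list(age = rep(NA_real_, n))
      hit <- !is.na(r$age)
      sum_age[hit] <- sum_age[hit] + r$age[hit]
      sum_frac[hit] <- sum_frac[hit] + iron_fraction(r$age[hit], efold)
      n_contact[hit] <- n_contact[hit] + 1
      n_seeded <- n_seeded + 1
    }
  }
  mean_age <- ifelse(n_contact > 0, sum_age / n_contact, NA_real_)
  mean_del <- ifelse(n_contact > 0, 100 * sum_frac / n_contact, NA_real_)
  shape <- function(x) matrix(x, length(seed_lon), length(seed_lat))
  structure(list(lon = seed_lon, lat = seed_lat,
                 mean_age = shape(mean_age), mean_delivery = shape(mean_del),
                 n_contact = shape(n_contact), n_seeded = shape(n_seeded)),
            class = "vb_delivery")
}

#' @export
print.vb_delivery <- function(x, ...) {
  cat(sprintf("<vb_delivery %d x %d seeds, %d node(s) with contact, delivery %.1f..%.1f %%>\n",
              length(x$lon), length(x$lat), sum(x$n_contact > 0),
              suppressWarnings(min(x$mean_delivery, na.rm = TRUE)),
              suppressWarnings(max(x$mean_delivery, na.rm = TRUE))))
  invisible(x)
}

#' Delivery-zone mask from a delivery map
#'
#' Thresholds a climatological delivery map into a 0/1 zone grid usable by
#' [classify_bloom()] as the shallow-source downstream-delivery zone.
#'
#' @param delivery a \code{vb_delivery}.
#' @param min_delivery_pct zone threshold, percent (default 10).
#' @return a \code{vb_grid} 0/1 mask.
#' @export
delivery_zone <- function(delivery, min_delivery_pct = 10) {
  z <- ifelse(!is.na(delivery$mean_delivery) &
                delivery$mean_delivery >= min_delivery_pct, 1, 0)
  field_grid(delivery$lon, delivery$lat,
             matrix(z, length(delivery$lon), length(delivery$lat)),
             "delivery_zone")
}
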