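# Potential-density climatology and alongstream isopycnal diagnosis:
# vertical binning of heterogeneous T/S profiles to standard levels,
# isotropic Gaussian optimal interpolation onto a half-degree grid,
# meridional section extraction, resampling to dynamic-height coordinate,
# and the alongstream density difference with pseudo-latitude mapping.

#' Bin hydrographic profiles to standard pressure levels
#'
#' Computes the potential density of each quality-controlled profile at
#' standard levels (default 0 to 2000 dbar every 25 dbar; 1 dbar is treated
#' as 1 m), with temperature and salinity linearly interpolated to the level
#' pressure. No extrapolation: levels outside the sampled range stay
#' missing. Profiles spanning fewer than two standard levels, or with a
#' quality flag other than 1, are dropped.
#'
#' @param hydro long data.frame from [read_hydrography()].
#' @param dz level spacing, dbar (default 25).
#' @param p_max deepest level, dbar (default 2000).
#' @return list: \code{levels} (dbar), \code{lon}, \code{lat} (one per kept
#'   profile), \code{sigma} matrix (profile x level, kg m^-3, NA outside
#'   sampled range).
#' @export
bin_profiles_vertical <- function(hydro, dz = 25, p_max = 2000) {
  hydro <- hydro[hydro$qc_flag == 1, , drop = FALSE]
  levels <- seq(0, p_max, by = dz)
  profs <- split(hydro, hydro$profile_id)
  keep <- logical(length(profs))
  sig <- matrix(NA_real_, length(profs), length(levels))
  lon <- lat <- numeric(length(profs))
  dropped <- 0
  for (k in seq_along(profs)) {
    d <- profs[[k]]
    d <- d[order(d$pres_dbar), , drop = FALSE]
    inrange <- levels >= min(d$pres_dbar) & levels <= max(d$pres_dbar)
    if (sum(inrange) < 2 || nrow(d) < 2) { dropped <- dropped + 1; next }
    keep[k] <- TRUE
    lon[k] <- normalize_lon(d$lon[1]); lat[k] <- d$lat[1]
    tI <- stats::approx(d$pres_dbar, d$temp_C, levels[inrange])$y
    sI <- stats::approx(d$pres_dbar, d$psal, levels[inrange])$y
    sig[k, inrange] <- potential_density(tI, sI, levels[inrange])
  }
  if (dropped) message(dropped, " profile(s) spanning < 2 standard levels dropped")
  list(levels = levels, lon = lon[keep], lat = lat[keep],
       sigma = sig[keep, , drop = FALSE])
}

#' Isotropic Gaussian optimal interpolation onto a regular grid
#'
#' Per level, the gridded value is the Gaussian-weighted mean of the samples,
#' weights \code{exp(-d^2 / (2 L^2))} with d the great-circle distance and L
#' the decorrelation scale; the effective data count n_eff is the total
#' weight, and nodes below the n_eff floor stay missing. This is the
#' isotropic simplification of the full mapping (no isobath-following
#' anisotropy, front sharpening, or recency weighting).
#'
#' @param lon,lat sample positions, degrees.
#' @param values sample matrix (sample x level) or vector.
#' @param grid_lon,grid_lat target grid coordinate vectors, degrees.
#' @param scale_km decorrelation scale, km (default 550).
#' @param neff_floor minimum effective count (default 0.2).
#' @return list: \code{grid_lon}, \code{grid_lat}, \code{field} array
#'   (lon x lat x level), \code{n_eff} matrix (lon x lat).
#' @export
optimal_interpolation <- function(lon, lat, values, grid_lon, grid_lat,
                                  scale_km = 550, neff_floor = 0.2) {
  values <- as.matrix(values)
  if (!nrow(values)) stop("no samples to interpolate")
  nodes <- expand.grid(lon = grid_lon, lat = grid_lat, KEEP.OUT.ATTRS = FALSE)
  d <- gc_dist_km(nodes$lon, nodes$lat, lon, lat)
  w <- exp(-d^2 / (2 * scale_km^2))
  present <- is.finite(values)
  vals0 <- ifelse(present, values, 0)
  num <- w %*% vals0                       # node x level
  den <- w %*% present
  fld <- num / den
  fld[den < neff_floor] <- NA_real_
  nl <- ncol(values)
  field <- array(fld, c(length(grid_lon), length(grid_lat), nl))
  n_eff <- matrix(rowSums(w), length(grid_lon), length(grid_lat))
  list(grid_lon = grid_lon, grid_lat = grid_lat, field = field, n_eff = n_eff)
}

#' Build a gridded potential-density climatology
#'
#' Chains [bin_profiles_vertical()] and [optimal_interpolation()] and
#' enforces stable stratification by sorting each node's density column
#' (convective adjustment of the climatology), flagging adjusted nodes.
#'
#' @param hydro long hydrography data.frame.
#' @param grid_lon,grid_lat grid coordinate vectors (default the 0-55E,
#'   55-45S sector at half-degree resolution).
#' @param dz level spacing, dbar (default 25).
#' @param scale_km decorrelation scale, km (default 550).
#' @param neff_floor minimum effective count (default 0.2).
#' @return a \code{vb_climatology}: \code{lon}, \code{lat}, \code{levels},
#'   \code{sigma} array (lon x lat x level), \code{n_eff},
#'   \code{sorted} logical matrix of nodes where sorting acted.
#' @export
build_density_climatology <- function(hydro,
                                      grid_lon = seq(0, 55, by = 0.5),
                                      grid_lat = seq(-55, -45, by = 0.5),
                                      dz = 25, scale_km = 550,
                                      neff_floor = 0.2) {
  b <- bin_profiles_vertical(hydro, dz = dz)
  oi <- optimal_interpolation(b$lon, b$lat, b$sigma, grid_lon, grid_lat,
                              scale_km, neff_floor)
  sig <- oi$field
  sorted <- matrix(FALSE, length(grid_lon), length(grid_lat))
  for (i in seq_along(grid_lon)) for (j in seq_along(grid_lat)) {
    col <- sig[i, j, ]
    ok <- is.finite(col)
    if (sum(ok) > 1 && is.unsorted(col[ok])) {
      sig[i, j, ok] <- sort(col[ok])
      sorted[i, j] <- TRUE
    }
  }
  structure(list(lon = grid_lon, lat = grid_lat, levels = b$levels,
                 sigma = sig, n_eff = oi$n_eff, sorted = sorted),
            class = "vb_climatology")
}

#' @export
print.vb_climatology <- function(x, ...) {
  cat(sprintf("<vb_climatology %d x %d x %d (lon x lat x level), %.0f-%.0f dbar>\n",
              length(x$lon), length(x$lat), length(x$levels),
              min(x$levels), max(x$levels)))
  invisible(x)
}

#' Extract a meridional density section from a climatology
#'
#' Bilinear sample of the climatology along a meridian at the grid's
#' latitude spacing.
#'
#' @param clim a \code{vb_climatology}.
#' @param lon section longitude, degrees.
#' @param lat_range latitude bounds (default 55S to 47S).
#' @return a \code{vb_section}: \code{lon}, \code{lat}, \code{levels},
#'   \code{sigma} matrix (lat x level).
#' @export
extract_section <- function(clim, lon, lat_range = c(-55, -47)) {
  lon <- normalize_lon(lon)
  if (lon < min(clim$lon) || lon > max(clim$lon))
    stop("section longitude ", lon, " outside climatology domain")
  lats <- clim$lat[clim$lat >= lat_range[1] & clim$lat <= lat_range[2]]
  sig <- matrix(NA_real_, length(lats), length(clim$levels))
  for (k in seq_along(clim$levels))
    sig[, k] <- bilinear_sample(clim$lon, clim$lat, clim$sigma[, , k],
                                rep(lon, length(lats)), lats)
  if (all(!is.finite(sig)))
    warning("section at ", lon, "E crosses an all-missing region")
  structure(list(lon = lon, lat = lats, levels = clim$levels, sigma = sig),
            class = "vb_section")
}

#' Resample a meridional section into dynamic-height coordinate
#'
#' Reindexes a density section from latitude to dynamic height using the
#' dh(lat) relation along the section, restricting to the largest monotone
#' envelope of dh(lat) when it is not monotone (excluded latitudes are
#' flagged). Comparing two sections at equal dynamic height compares the
#' same streamline, i.e. alongstream.
#'
#' @param section a \code{vb_section}.
#' @param dh dynamic height at the section latitudes (same length/order as
#'   \code{section$lat}).
#' @param dh_axis target dh axis; defaults to 60 points spanning the
#'   section's dh range.
#' @return a \code{vb_section_dh}: \code{dh}, \code{levels}, \code{sigma}
#'   (dh x level), \code{excluded_lat}.
#' @export
to_dh_coordinate <- function(section, dh, dh_axis = NULL) {
  stopifnot(length(dh) == length(section$lat))
  ok <- is.finite(dh)
  excluded <- section$lat[!ok]
  lat <- section$lat[ok]; dhv <- dh[ok]
  sig <- section$sigma[ok, , drop = FALSE]
  if (length(dhv) > 1 && any(diff(dhv) <= 0)) {
    if (any(diff(dhv) >= 0)) {
      # keep the largest strictly monotone run
      s <- sign(diff(dhv))
      dir <- if (sum(s > 0) >= sum(s < 0)) 1 else -1
      runs <- rle(s == dir)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      best <- which.max(ifelse(runs$values, runs$lengths, 0))
      idx <- starts[best]:(ends[best] + 1)
      excluded <- c(excluded, lat[-idx])
      lat <- lat[idx]; dhv <- dhv[idx]
      sig <- sig[idx, , drop = FALSE]
    }
  }
  if (length(dhv) < 2) stop("dh(lat) leaves fewer than 2 usable latitudes")
  if (is.null(dh_axis))
    dh_axis <- seq(min(dhv), max(dhv), length.out = 60)
  out <- matrix(NA_real_, length(dh_axis), ncol(sig))
  for (k in seq_len(ncol(sig))) {
    okk <- is.finite(sig[, k])
    if (sum(okk) >= 2)
      out[, k] <- stats::approx(dhv[okk], sig[okk, k], dh_axis, rule = 1)$y
  }
  structure(list(dh = dh_axis, levels = section$levels, sigma = out,
                 excluded_lat = excluded),
            class = "vb_section_dh")
}

#' Alongstream density difference between two sections
#'
#' Differences two meridional density sections on a common dynamic-height
#' axis (downstream minus upstream: positive at depth means isopycnals
#' shoal downstream) and maps the dh axis back to a pseudo-latitude through
#' the inverted sector-mean dh(lat) relation (piecewise linear, with
#' isotonic correction when the sector mean is not monotone).
#'
#' @param sec_down,sec_up \code{vb_section} objects (downstream, upstream).
#' @param dh_down,dh_up dynamic height along each section's latitudes.
#' @param sector_lat,sector_dh sector-mean dh(lat) relation used for the
#'   pseudo-latitude mapping.
#' @param n_dh dh-axis resolution (default 60).
#' @return a \code{vb_dsigma}: \code{dh}, \code{pseudo_lat}, \code{levels},
#'   \code{delta_sigma} (dh x level, kg m^-3), \code{isotonic_applied}.
#' @export
alongstream_delta_sigma <- function(sec_down, sec_up, dh_down, dh_up,
                                    sector_lat, sector_dh, n_dh = 60) {
  lo <- max(min(dh_down, na.rm = TRUE), min(dh_up, na.rm = TRUE))
  hi <- min(max(dh_down, na.rm = TRUE), max(dh_up, na.rm = TRUE))
  if (!(hi > lo)) stop("dynamic-height ranges of the two sections do not overlap")
  axis <- seq(lo, hi, length.out = n_dh)
  a <- to_dh_coordinate(sec_down, dh_down, axis)
  b <- to_dh_coordinate(sec_up, dh_up, axis)
  dsig <- a$sigma - b$sigma
  ord <- order(sector_dh)
  sdh <- sector_dh[ord]; slat <- sector_lat[ord]
  iso <- FALSE
  if (any(diff(slat) < 0)) {
    iso <- TRUE
    slat <- stats::isoreg(sdh, slat)$yf
  }
  pseudo_lat <- stats::approx(sdh, slat, axis, rule = 2)$y
  structure(list(dh = axis, pseudo_lat = pseudo_lat,
                 levels = sec_down$levels, delta_sigma = dsig,
                 isotonic_applied = iso,
                 orientation = "downstream minus upstream"),
            class = "vb_dsigma")
}

#' @export
print.vb_dsigma <- function(x, ...) {
  rng <- range(x$delta_sigma, na.rm = TRUE)
  cat(sprintf("<vb_dsigma %d dh x %d levels, delta-sigma %.3f..%.3f kg m-3 (%s)>\n",
              length(x$dh), length(x$levels), rng[1], rng[2], x$orientation))
  invisible(x)
}
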