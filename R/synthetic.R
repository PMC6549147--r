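# Synthetic-data generators. Every generator is a pure function of
# (parameters, seed) and returns its inputs together with a ground-truth
# ledger sufficient for parameter-recovery assertions downstream: prescribed
# bloom magnitude, analytic eddy kinetic energy, alongstream density
# contrast, and plume shape.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# invert sigma0 -> in-situ temperature at fixed salinity and pressure by
# table lookup (sigma0 is strictly decreasing in T over the oceanic range)
invert_sigma_to_temp <- function(sigma_target, psal, pres) {
  Tg <- seq(-2.4, 28, by = 0.05)
  out <- numeric(length(sigma_target))
  for (p in unique(pres)) {
    sg <- sw_dens(psal, sw_ptmp(psal, Tg, p, 0), 0) - 1000
    sel <- pres == p
    out[sel] <- stats::approx(sg, Tg, sigma_target[sel], rule = 2)$y
  }
  out
}

#' Generate a synthetic bio-optical float series
#'
#' Emulates a float sampling an annual bloom: chlorophyll is a Gaussian
#' pulse in time, vertically homogeneous within a prescribed mixed layer and
#' decaying exponentially below it. Daytime casts have all levels strictly
#' shallower than the mixed layer multiplied by (1 - quench_fraction),
#' emulating non-photochemical quenching; the cast level at the mixed-layer
#' base stays unquenched. Fluorescence counts are chl / (f490 * slope) +
#' dark, so factory-calibrated values overestimate truth by 1/f490. T/S are
#' a two-layer structure whose density-threshold mixed layer equals the
#' prescribed one.
#'
#' The prescribed bloom magnitude is the depth-integrated chlorophyll at the
#' bloom peak over the mixed layer, the quantity the bloom-phenology chain
#' recovers up to 20-day-bin smoothing.
#'
#' @param n_seasons number of annual cycles (default 1).
#' @param bloom_magnitude peak depth-integrated chlorophyll, mg m^-2.
#' @param bloom_center_doy day of bloom peak counted from 1 July (default
#'   184, i.e. 1 January).
#' @param bloom_sd_days temporal standard deviation of the pulse, days.
#' @param bloom_depth_scale e-folding depth of chlorophyll below the mixed
#'   layer, m.
#' @param mld_true prescribed mixed layer depth, m (a sampled level).
#' @param noise_sd chlorophyll noise, mg m^-3.
#' @param quench_fraction daytime surface quenching fraction, 0 to 1.
#' @param cal a \code{vb_calibration} (the generating truth).
#' @param cadence_days days between casts (default 10).
#' @param depths sampled depths, m (default 5-250 every 5).
#' @param start_year first season's starting year (default 2014).
#' @param lat,lon nominal float position.
#' @param float_id float identifier.
#' @param seed RNG seed.
#' @return list \code{profiles} (list of \code{vb_profile}) and \code{truth}
#'   (bloom magnitude, mixed layer, calibration, seed).
#' @export
gen_float_series <- function(n_seasons = 1, bloom_magnitude = 80,
                             bloom_center_doy = 184, bloom_sd_days = 40,
                             bloom_depth_scale = 15, mld_true = 100,
                             noise_sd = 0, quench_fraction = 0,
                             cal = calibration_spec(),
                             cadence_days = 10,
                             depths = seq(5, 250, by = 5),
                             start_year = 2014, lat = -50, lon = 32,
                             float_id = "SYN0001", seed = 1) {
  stopifnot(bloom_magnitude > 0, bloom_sd_days > 0, bloom_depth_scale > 0,
            quench_fraction >= 0, quench_fraction <= 1)
  if (!all(is.finite(c(bloom_magnitude, bloom_center_doy, bloom_sd_days,
                       bloom_depth_scale, mld_true, noise_sd))))
    stop("non-finite generator parameter")
  if (!mld_true %in% depths)
    stop("mld_true must coincide with a sampled depth")
  base_chl <- 0.02
  A0 <- bloom_magnitude / mld_true          # peak surface chlorophyll
  # two-layer density: surface 26.80, +0.5 jump across the mixed-layer base
  sigma_of_z <- function(z) {
    26.80 + ifelse(z <= mld_true, 0,
                   pmin((z - mld_true) / 5, 1) * 0.5 +
                     pmax(z - mld_true - 5, 0) * 0.002)
  }
  temp <- invert_sigma_to_temp(sigma_of_z(depths), 34.2, depths)
  with_seed(seed, {
    profiles <- list()
    for (s in seq_len(n_seasons)) {
      season0 <- as.Date(sprintf("%d-07-01", start_year + s - 1))
      tdays <- seq(0, 364, by = cadence_days)
      for (k in seq_along(tdays)) {
        day <- tdays[k]
        amp <- base_chl + (A0 - base_chl) *
          exp(-(day - bloom_center_doy)^2 / (2 * bloom_sd_days^2))
        chl <- ifelse(depths <= mld_true, amp,
                      amp * exp(-(depths - mld_true) / bloom_depth_scale))
        if (noise_sd > 0) chl <- pmax(chl + stats::rnorm(length(chl), 0, noise_sd), 0)
        day_flag <- k %% 2 == 1
        fluo_chl <- chl
        if (day_flag && quench_fraction > 0)
          fluo_chl[depths < mld_true] <- fluo_chl[depths < mld_true] *
            (1 - quench_fraction)
        fluo <- fluo_chl / (cal$f490 * cal$slope) + cal$dark
        profiles[[length(profiles) + 1]] <- new_profile(
          float_id = float_id, cycle = length(profiles) + 1L,
          time = as.POSIXct(season0, tz = "UTC") + day * 86400 + 43200,
          lat = lat + stats::runif(1, -0.05, 0.05),
          lon = normalize_lon(lon + stats::runif(1, -0.05, 0.05)),
          day_flag = day_flag,
          pres = depths, temp = temp, psal = rep(34.2, length(depths)),
          fluo = fluo, bbp700 = 0.0004 + 0.002 * chl)
      }
    }
    list(profiles = profiles,
         truth = list(bloom_magnitude_true = bloom_magnitude,
                      mld_true = mld_true,
                      peak_surface_chl = A0,
                      bloom_center_doy = bloom_center_doy,
                      bloom_sd_days = bloom_sd_days,
                      cal = unclass(cal), rng_seed = seed))
  })
}

#' Generate an analytic gridded velocity series
#'
#' Three named flows with analytic truth:
#' \describe{
#'   \item{solid_body}{rigid rotation of the coordinate plane about a
#'     center: dlon/dt = -omega (lat - lat0), dlat/dt = omega (lon - lon0)
#'     with omega = 2 pi / period. Trajectories are exactly closed circles
#'     in lon/lat space with the prescribed period — the integrator oracle.
#'     Stored velocities are the metric-consistent m/s values.}
#'   \item{zonal_jet}{u = U sech^2((lat - lat0)/L), v = 0.}
#'   \item{jet_plus_eddies}{the jet plus a zonally propagating eddy train
#'     u' = A sin(k lon - w t + phase), v' = A cos(k lon - w t + phase);
#'     each component's time variance is A^2/2, so the true surface EKE is
#'     A^2/2 (m^2 s^-2) = 1e4 A^2/2 cm^2 s^-2.}
#' }
#'
#' @param kind flow kind.
#' @param lon,lat grid coordinate vectors, degrees.
#' @param time time axis, days since 2000-01-01.
#' @param center_lon,center_lat rotation center (solid_body).
#' @param period_days rotation period (solid_body).
#' @param jet_u0 jet peak speed, m s^-1.
#' @param jet_lat0,jet_width_deg jet axis and width.
#' @param eddy_amp eddy amplitude A, m s^-1.
#' @param eddy_period_days,eddy_wavelength_deg eddy train period/wavelength.
#' @param phase eddy phase, radians.
#' @param seed RNG seed (kept for interface symmetry; fields are analytic).
#' @return list \code{series} (a \code{vb_velocity}) and \code{truth}.
#' @export
gen_velocity_series <- function(kind = c("solid_body", "zonal_jet",
                                         "jet_plus_eddies"),
                                lon, lat, time,
                                center_lon = mean(lon), center_lat = mean(lat),
                                period_days = 30,
                                jet_u0 = 0.25, jet_lat0 = mean(lat),
                                jet_width_deg = 2,
                                eddy_amp = 0.2, eddy_period_days = 10,
                                eddy_wavelength_deg = 5, phase = 0,
                                seed = 1) {
  kind <- match.arg(kind)
  nlon <- length(lon); nlat <- length(lat); nt <- length(time)
  L <- matrix(lon, nlon, nlat); P <- matrix(lat, nlon, nlat, byrow = TRUE)
  u <- array(NA_real_, c(nlon, nlat, nt)); v <- u
  truth <- list(kind = kind, rng_seed = seed)
  if (kind == "solid_body") {
    omega <- 2 * pi / period_days                 # radians per day
    uslice <- -omega * (P - center_lat) * m_per_deg_lon(P) / 86400
    vslice <- omega * (L - center_lon) * m_per_deg_lat(P) / 86400
    for (k in seq_len(nt)) { u[, , k] <- uslice; v[, , k] <- vslice }
    truth$period_days <- period_days
    truth$center <- c(center_lon, center_lat)
    truth$velocity_fun <- function(lo, la, t)
      list(u = -omega * (la - center_lat) * m_per_deg_lon(la) / 86400,
           v = omega * (lo - center_lon) * m_per_deg_lat(la) / 86400)
  } else {
    ujet <- jet_u0 / cosh((P - jet_lat0) / jet_width_deg)^2
    if (kind == "zonal_jet") {
      for (k in seq_len(nt)) { u[, , k] <- ujet; v[, , k] <- 0 }
      truth$eke_true_cm2s2 <- 0
    } else {
      kx <- 2 * pi / eddy_wavelength_deg
      w <- 2 * pi / eddy_period_days
      for (k in seq_len(nt)) {
        ph <- kx * L - w * time[k] + phase
        u[, , k] <- ujet + eddy_amp * sin(ph)
        v[, , k] <- eddy_amp * cos(ph)
      }
      truth$eke_true_cm2s2 <- eddy_amp^2 / 2 * 1e4
      truth$eddy_amp <- eddy_amp
      truth$eddy_period_days <- eddy_period_days
    }
  }
  list(series = velocity_series(lon, lat, time, u, v), truth = truth)
}

#' Generate deep-displacement records with known velocity statistics
#'
#' Endpoint pairs consistent with velocity = mean flow + isotropic Gaussian
#' noise over one park cycle, placed uniformly in a box. The true deep EKE
#' is noise_sd^2 (half the sum of the two component variances, each
#' noise_sd^2), i.e. 1e4 * noise_sd^2 in cm^2 s^-2.
#'
#' @param n record count.
#' @param mean_u,mean_v mean flow, m s^-1.
#' @param noise_sd per-component velocity noise, m s^-1.
#' @param lon_range,lat_range deployment box, degrees.
#' @param cycle_days park-cycle duration, days.
#' @param park_pres park pressure, dbar.
#' @param seed RNG seed.
#' @return list \code{displacements} (data.frame) and \code{truth}.
#' @export
gen_displacements <- function(n, mean_u = 0, mean_v = 0, noise_sd = 0.1,
                              lon_range = c(30, 31), lat_range = c(-51, -50),
                              cycle_days = 10, park_pres = 1000, seed = 1) {
  stopifnot(n >= 1, noise_sd >= 0, cycle_days > 0)
  with_seed(seed, {
    lon0 <- stats::runif(n, lon_range[1], lon_range[2])
    lat0 <- stats::runif(n, lat_range[1], lat_range[2])
    u <- mean_u + stats::rnorm(n, 0, noise_sd)
    v <- mean_v + stats::rnorm(n, 0, noise_sd)
    dt <- cycle_days * 86400
    dlat <- v * dt / m_per_deg_lat(lat0)
    latbar <- lat0 + dlat / 2
    dlon <- u * dt / m_per_deg_lon(latbar)
    t0 <- as.POSIXct("2015-01-01", tz = "UTC") + (seq_len(n) - 1) * 3600
    df <- data.frame(float_id = sprintf("SYND%04d", (seq_len(n) - 1) %% 50 + 1),
                     cycle = seq_len(n), park_pres_dbar = park_pres,
                     t0 = t0, lon0 = lon0, lat0 = lat0,
                     t1 = t0 + dt, lon1 = lon0 + dlon, lat1 = lat0 + dlat)
    list(displacements = df,
         truth = list(eke_true_cm2s2 = noise_sd^2 * 1e4,
                      mean_u = mean_u, mean_v = mean_v, rng_seed = seed))
  })
}

#' Generate a hydrographic profile set with prescribed alongstream tilt
#'
#' Potential density is background(P) plus a linear meridional gradient plus
#' tilt * (lon - lon_ref)/10 * shape(P), with shape a Gaussian in pressure
#' peaking at \code{shape_peak_dbar} (value 1 there), plus noise. The
#' alongstream density contrast between two sections dlon degrees apart is
#' analytically tilt * dlon/10 * shape(P). A \code{meander_deg} option
#' displaces the whole density and dynamic-height structure northward
#' downstream without water-mass change (both fields depend on latitude only
#' through lat - shift(lon)), the null case for the dynamic-height-coordinate
#' comparison.
#'
#' @param tilt alongstream contrast, kg m^-3 per 10 degrees longitude.
#' @param n_profiles profile count.
#' @param lon_range,lat_range sampling region, degrees.
#' @param noise_sd density noise, kg m^-3.
#' @param lon_ref tilt reference longitude (default 28).
#' @param shape_peak_dbar pressure of maximum contrast (default 750).
#' @param shape_width_dbar Gaussian width of the contrast (default 400).
#' @param merid_grad meridional density gradient, kg m^-3 per degree lat.
#' @param meander_deg northward displacement of the structure at the east
#'   edge of the region (default 0).
#' @param qc_bad_fraction fraction of profiles flagged with qc 4.
#' @param seed RNG seed.
#' @return list \code{hydro} (long data.frame), \code{dh} (a \code{vb_grid}
#'   of dynamic height, dyn m), and \code{truth} (including
#'   \code{delta_sigma_fun(P, dlon)}).
#' @export
gen_hydrography <- function(tilt = 0.2, n_profiles = 3000,
                            lon_range = c(0, 55), lat_range = c(-55, -45),
                            noise_sd = 0.01, lon_ref = 28,
                            shape_peak_dbar = 750, shape_width_dbar = 400,
                            merid_grad = 0.08, meander_deg = 0,
                            qc_bad_fraction = 0.02, seed = 1) {
  stopifnot(n_profiles >= 1, noise_sd >= 0)
  levels <- seq(0, 2000, by = 25)
  shape <- function(P) exp(-(P - shape_peak_dbar)^2 / (2 * shape_width_dbar^2))
  shift <- function(lon) meander_deg * (lon - lon_range[1]) /
    (lon_range[2] - lon_range[1])
  sigma_fun <- function(P, lat, lon) {
    lat_eff <- lat - shift(lon)
    26.2 + 1.1 * (1 - exp(-P / 800)) + merid_grad * (-lat_eff - 50) +
      tilt * (lon - lon_ref) / 10 * shape(P)
  }
  dh_fun <- function(lat, lon) 0.1 * (lat - shift(lon) + 55)
  with_seed(seed, {
    lon <- stats::runif(n_profiles, lon_range[1], lon_range[2])
    lat <- stats::runif(n_profiles, lat_range[1], lat_range[2])
    qc <- ifelse(stats::runif(n_profiles) < qc_bad_fraction, 4L, 1L)
    src <- sample(c("ship", "float", "animal"), n_profiles, replace = TRUE,
                  prob = c(0.3, 0.5, 0.2))
    t0 <- as.POSIXct("2005-01-01", tz = "UTC")
    nl <- length(levels)
    sig <- outer(seq_len(n_profiles), seq_len(nl),
                 function(i, k) sigma_fun(levels[k], lat[i], lon[i]))
    if (noise_sd > 0) sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
    # invert to T at fixed salinity so the density chain is exercised
    pres_all <- rep(levels, times = n_profiles)
    temp_all <- invert_sigma_to_temp(as.vector(t(sig)), 34.3, pres_all)
    hydro <- data.frame(
      profile_id = rep(sprintf("H%05d", seq_len(n_profiles)), each = nl),
      source = rep(src, each = nl),
      qc_flag = rep(qc, each = nl),
      time = t0 + rep(stats::runif(n_profiles, 0, 3650), each = nl) * 86400,
      lat = rep(lat, each = nl), lon = rep(lon, each = nl),
      pres_dbar = pres_all, temp_C = temp_all, psal = 34.3)
    dlon_g <- seq(lon_range[1], lon_range[2], by = 0.5)
    dlat_g <- seq(lat_range[1], lat_range[2], by = 0.5)
    dh <- field_grid(dlon_g, dlat_g,
                     outer(dlon_g, dlat_g, function(lo, la) dh_fun(la, lo)),
                     "dh_dyn_m")
    list(hydro = hydro, dh = dh,
         truth = list(tilt = tilt, shape_peak_dbar = shape_peak_dbar,
                      delta_sigma_fun = function(P, dlon)
                        tilt * dlon / 10 * shape(P),
                      meander_deg = meander_deg, merid_grad = merid_grad,
                      dh_fun = dh_fun, sigma_fun = sigma_fun,
                      rng_seed = seed))
  })
}

#' Generate helium-isotope tracer stations with a prescribed plume
#'
#' The tracer anomaly is Gaussian in depth about the plume core, decays
#' exponentially only downstream (east) of the ridge, and relaxes to a small
#' background that vanishes above the thermocline (air-sea equilibration).
#'
#' @param stations data.frame \code{lon, lat} in along-track order.
#' @param plume_center_depth plume core depth, m.
#' @param plume_peak core anomaly at the ridge, percent.
#' @param plume_width_m Gaussian depth width, m.
#' @param decay_scale_km downstream e-folding distance, km.
#' @param ridge_lon ridge longitude, degrees.
#' @param background deep background anomaly, percent.
#' @param thermocline_depth depth above which the background fades, m.
#' @param depths sampled depths, m.
#' @param noise_sd measurement noise, percent.
#' @param seed RNG seed.
#' @return list \code{stations} (as [read_tracer_stations()]) and
#'   \code{truth}.
#' @export
gen_tracer_stations <- function(stations = data.frame(lon = seq(27, 39, by = 2),
                                                      lat = -50),
                                plume_center_depth = 2300, plume_peak = 11,
                                plume_width_m = 500, decay_scale_km = 1500,
                                ridge_lon = 30, background = 2,
                                thermocline_depth = 500,
                                depths = seq(0, 3500, by = 125),
                                noise_sd = 0, seed = 1) {
  if (!nrow(stations)) stop("stations must be nonempty")
  with_seed(seed, {
    out <- lapply(seq_len(nrow(stations)), function(i) {
      lo <- stations$lon[i]; la <- stations$lat[i]
      bg <- background * pmin(depths / thermocline_depth, 1)
      amp <- if (lo >= ridge_lon) {
        d_km <- gc_dist_km(lo, la, ridge_lon, la)[1, 1]
        plume_peak * exp(-d_km / decay_scale_km)
      } else 0
      v <- bg + amp * exp(-(depths - plume_center_depth)^2 / (2 * plume_width_m^2))
      if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
      list(cruise = "SYNTH01", station = sprintf("S%02d", i),
           lat = la, lon = normalize_lon(lo), depth = depths, delta3he = v)
    })
    list(stations = out,
         truth = list(plume_peak = plume_peak,
                      plume_center_depth = plume_center_depth,
                      decay_scale_km = decay_scale_km,
                      ridge_lon = ridge_lon, rng_seed = seed))
  })
}

#' Generate analytic fixture bathymetry
#'
#' A 4000 m abyssal plain with a Gaussian-in-longitude ridge (crest
#' shallower than 2000 m) and a shelf shallower than 500 m at the eastern
#' domain edge, exercising both iron-source kinds.
#'
#' @param lon_range,lat_range domain, degrees.
#' @param res_deg grid resolution (default 0.25).
#' @param ridge_lon ridge axis longitude.
#' @param ridge_width_deg Gaussian width.
#' @param crest_depth ridge crest depth, m.
#' @param shelf_lon longitudes east of this are shelf.
#' @param shelf_depth shelf depth, m.
#' @return a \code{vb_grid} of depth (m, positive down).
#' @export
gen_bathymetry <- function(lon_range = c(20, 55), lat_range = c(-55, -45),
                           res_deg = 0.25, ridge_lon = 30,
                           ridge_width_deg = 1.5, crest_depth = 1500,
                           shelf_lon = 52, shelf_depth = 300) {
  lon <- seq(lon_range[1], lon_range[2], by = res_deg)
  lat <- seq(lat_range[1], lat_range[2], by = res_deg)
  z <- outer(lon, lat, function(lo, la) {
    d <- 4000 - (4000 - crest_depth) * exp(-((lo - ridge_lon) / ridge_width_deg)^2)
    ifelse(lo >= shelf_lon, shelf_depth, d)
  })
  field_grid(lon, lat, z, "depth_m")
}

#' Write the full synthetic fixture set
#'
#' Generates one of every input kind with the default study conditions and
#' writes them (plus the ground-truth ledger as JSON) to a directory.
#' Regenerating with the same seed reproduces byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed; sub-generators derive fixed offsets from it.
#' @return invisibly, the truth list.
#' @export
simulate_fixture_set <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- gen_float_series(seed = seed)
  write_profile_series(fs$profiles, file.path(dir, "profiles.csv"))
  gv <- gen_velocity_series("jet_plus_eddies",
                            lon = seq(20, 45, by = 1), lat = seq(-55, -45, by = 1),
                            time = seq(0, 59, by = 1), seed = seed + 1)
  write_velocity_series(gv$series, file.path(dir, "velocity.csv"))
  gd <- gen_displacements(n = 2000, noise_sd = 0.1, seed = seed + 2)
  write_displacements(gd$displacements, file.path(dir, "displacements.csv"))
  gh <- gen_hydrography(n_profiles = 800, seed = seed + 3)
  write_hydrography(gh$hydro, file.path(dir, "hydrography.csv"))
  write_field_grid(gh$dh, file.path(dir, "dh.csv"))
  gt <- gen_tracer_stations(seed = seed + 4)
  write_tracer_stations(gt$stations, file.path(dir, "tracer.csv"))
  bathy <- gen_bathymetry()
  write_field_grid(bathy, file.path(dir, "bathymetry.csv"))
  truth <- list(float = fs$truth, velocity = gv$truth,
                displacements = gd$truth,
                hydrography = gh$truth[c("tilt", "shape_peak_dbar",
                                         "meander_deg", "merid_grad",
                                         "rng_seed")],
                tracer = gt$truth, rng_seed = seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}
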