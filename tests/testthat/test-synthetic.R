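# Generators: seeded determinism, construction identities, and analytic
# ground truth verified against independent numerical oracles.

test_that("generators are pure functions of parameters and seed", {
  a <- gen_float_series(seed = 12)
  b <- gen_float_series(seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, gen_float_series(seed = 13)))

  d1 <- gen_displacements(50, seed = 3)
  d2 <- gen_displacements(50, seed = 3)
  expect_identical(d1, d2)

  h1 <- gen_hydrography(n_profiles = 10, seed = 5)
  h2 <- gen_hydrography(n_profiles = 10, seed = 5)
  expect_identical(h1$hydro, h2$hydro)
})

test_that("generators restore the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_displacements(10, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("synthetic float series matches its closed-form construction", {
  fs <- gen_float_series(bloom_magnitude = 80, quench_fraction = 0.4,
                         noise_sd = 0, seed = 8)
  tr <- fs$truth
  # independent oracle: analytic amplitude envelope at each cast time
  amp <- function(day) 0.02 + (tr$peak_surface_chl - 0.02) *
    exp(-(day - tr$bloom_center_doy)^2 / (2 * tr$bloom_sd_days^2))
  season0 <- as.POSIXct("2014-07-01", tz = "UTC")
  cal <- calibration_spec(tr$cal$dark, tr$cal$slope, tr$cal$f490)
  for (p in fs$profiles[c(2, 19, 37)]) {
    # casts are timestamped at noon of their sampling day
    day <- as.numeric(difftime(p$time, season0, units = "days")) - 0.5
    chl <- calibrate_chl(p$fluo, cal)
    if (!p$day_flag) {
      # night cast: no quenching; surface chl equals the envelope exactly
      expect_equal(chl[1], amp(day), tolerance = 1e-10)
      # quenching correction is the identity on it
      expect_equal(npq_correct(p, tr$mld_true), p$fluo)
    }
  }
  # a day cast near the bloom center is quenched above the mixed layer only
  pday <- fs$profiles[[19]]
  expect_true(pday$day_flag)
  chl_day <- calibrate_chl(pday$fluo, cal)
  day <- as.numeric(difftime(pday$time, season0, units = "days")) - 0.5
  expect_equal(chl_day[pday$pres < tr$mld_true][1], 0.6 * amp(day),
               tolerance = 1e-10)
  expect_equal(chl_day[pday$pres == tr$mld_true], amp(day), tolerance = 1e-10)
})

test_that("factory-calibrated chlorophyll overestimates truth by 1/f490", {
  fs <- gen_float_series(bloom_magnitude = 80, seed = 8)
  p <- fs$profiles[[20]]
  cal <- fs$truth$cal
  factory <- calibrate_chl(p$fluo, calibration_spec(cal$dark, cal$slope, 1))
  corrected <- calibrate_chl(p$fluo, calibration_spec(cal$dark, cal$slope,
                                                      cal$f490))
  expect_equal(factory / corrected, rep(1 / 0.3, length(factory)),
               tolerance = 1e-12)
})

test_that("analytic velocity fields match their definitions on grid nodes", {
  lon <- seq(25, 35, 1); lat <- seq(-54, -46, 1)
  gz <- gen_velocity_series("zonal_jet", lon, lat, time = 0:3, jet_u0 = 0.25,
                            jet_lat0 = -50, jet_width_deg = 2)
  expect_true(all(gz$series$v == 0))
  expect_equal(max(gz$series$u), 0.25)
  expect_equal(gz$series$u[1, , 1],
               0.25 / cosh((lat + 50) / 2)^2, tolerance = 1e-12)

  gs <- gen_velocity_series("solid_body", lon, lat, time = 0:1,
                            center_lon = 30, center_lat = -50,
                            period_days = 30)
  om <- 2 * pi / 30
  i <- which(lon == 30); j <- which(lat == -49)
  expect_equal(gs$series$v[i, j, 1], 0)
  expect_equal(gs$series$u[i, j, 1],
               -om * 1 * 6371000 * pi / 180 * cos(-49 * pi / 180) / 86400)
})

test_that("eddy-train surface EKE truth equals the sinusoid variance half-sum", {
  # long-sample numerical variance oracle for the analytic truth A^2/2
  ge <- gen_velocity_series("jet_plus_eddies", lon = seq(25, 30, 1),
                            lat = seq(-52, -48, 1),
                            time = seq(0, 400, by = 0.25),
                            eddy_amp = 0.15, eddy_period_days = 10)
  u <- ge$series$u[3, 3, ]; v <- ge$series$v[3, 3, ]
  num_eke <- (mean((u - mean(u))^2) + mean((v - mean(v))^2)) / 2 * 1e4
  expect_equal(num_eke, ge$truth$eke_true_cm2s2, tolerance = 1e-6)
  expect_equal(ge$truth$eke_true_cm2s2, 0.15^2 / 2 * 1e4)
})

test_that("noise-free displacements invert exactly to the mean flow", {
  gd <- gen_displacements(25, mean_u = 0.07, mean_v = -0.03, noise_sd = 0,
                          seed = 6)
  vel <- displacement_velocity(gd$displacements)
  expect_equal(vel$u, rep(7, 25), tolerance = 1e-10)
  expect_equal(vel$v, rep(-3, 25), tolerance = 1e-10)
})

test_that("hydrography samples reproduce the prescribed density field", {
  gh <- gen_hydrography(tilt = 0.2, n_profiles = 12, noise_sd = 0,
                        qc_bad_fraction = 0, seed = 7)
  b <- bin_profiles_vertical(gh$hydro)
  # casts sampled exactly at standard levels: interpolation is the identity,
  # so binned sigma equals the generator field up to the T-inversion table
  for (i in c(1, 5, 12)) {
    truth <- gh$truth$sigma_fun(b$levels, b$lat[i], b$lon[i])
    expect_equal(b$sigma[i, ], truth, tolerance = 1e-4)
  }
  # alongstream contrast of the construction
  expect_equal(gh$truth$delta_sigma_fun(750, 10), 0.2)
  expect_lt(gh$truth$delta_sigma_fun(0, 10), 0.2 * 0.2)
  g0 <- gen_hydrography(tilt = 0, n_profiles = 4, noise_sd = 0, seed = 7)
  expect_equal(g0$truth$delta_sigma_fun(750, 10), 0)
})

test_that("tracer stations encode the plume construction", {
  sts <- data.frame(lon = c(26, 30, 38), lat = -50)
  gt <- gen_tracer_stations(stations = sts, plume_peak = 11, background = 0,
                            decay_scale_km = 1500, ridge_lon = 30,
                            plume_center_depth = 2250,
                            depths = seq(0, 3500, 125), seed = 1)
  west <- gt$stations[[1]]; ridge <- gt$stations[[2]]; east <- gt$stations[[3]]
  expect_true(all(abs(west$delta3he) < 1e-12))  # upstream of the ridge
  expect_equal(max(ridge$delta3he), 11)
  expect_equal(ridge$depth[which.max(ridge$delta3he)], 2250)
  # one decay scale downstream: peak ratio e^-1; the along-parallel offset
  # converts to great-circle distance by the spherical law of cosines
  dlam <- 1500 / (111.1949 * cos(-50 * pi / 180)) * pi / 180
  phi <- -50 * pi / 180
  d_gc <- acos(sin(phi)^2 + cos(phi)^2 * cos(dlam)) * 6371
  sts2 <- data.frame(lon = c(30, 30 + dlam * 180 / pi), lat = -50)
  gt2 <- gen_tracer_stations(stations = sts2, plume_peak = 11, background = 0,
                             decay_scale_km = 1500, ridge_lon = 30, seed = 1)
  expect_equal(max(gt2$stations[[2]]$delta3he) / max(gt2$stations[[1]]$delta3he),
               exp(-d_gc / 1500), tolerance = 1e-3)
})

test_that("fixture bathymetry exposes ridge, abyssal plain, and shelf", {
  b <- gen_bathymetry()
  expect_lt(min(b$z), 2000)          # ridge crest shallower than 2000 m
  expect_equal(max(b$z), 4000)       # abyssal plain
  shelf <- b$z[b$lon >= 52.5, ]
  expect_true(all(shelf < 500))      # shallow-source shelf at the east edge
  interior <- b$z[b$lon > 34 & b$lon < 50, ]
  expect_true(all(interior > 3000))
})

test_that("generator parameter validation rejects nonsense", {
  expect_error(gen_float_series(bloom_magnitude = -5), "bloom_magnitude")
  expect_error(gen_float_series(bloom_sd_days = NA),
               "bloom_sd_days|non-finite|missing")
  expect_error(gen_displacements(0), "n >= 1")
  expect_error(gen_tracer_stations(stations = data.frame()), "nonempty")
})
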