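# Backward Lagrangian advection, source-contact search, and scavenging.

test_that("velocity interpolation is exact at nodes and linear in time", {
  lon <- seq(28, 32, 1); lat <- seq(-52, -48, 1)
  dm <- c(5, 5, 2)
  u <- array(0, dm); u[, , 2] <- 0.2
  ser <- velocity_series(lon, lat, c(0, 10), u, array(0, dm))
  expect_equal(interp_velocity(ser, 30, -50, 0)$u, 0)
  expect_equal(interp_velocity(ser, 30, -50, 10)$u, 0.2)
  expect_equal(interp_velocity(ser, 30, -50, 5)$u, 0.1)
  expect_error(interp_velocity(ser, 30, -50, 11), "outside")
})

test_that("land neighbors get zero weight and full-land queries beach", {
  lon <- c(29, 30); lat <- c(-51, -50)
  u <- array(c(0.1, NA, 0.1, NA), c(2, 2, 1))   # land at lon=30 column
  ser <- velocity_series(lon, lat, 0, u, array(0, c(2, 2, 1)))
  # midway: renormalized over the wet column
  expect_equal(interp_velocity(ser, 29.5, -50.5, 0)$u, 0.1)
  uall <- array(NA_real_, c(2, 2, 1))
  serall <- velocity_series(lon, lat, 0, uall, uall)
  expect_true(is.na(interp_velocity(serall, 29.5, -50.5, 0)$u))
  st <- rk4_step(29.5, -50.5, 0, 6, serall)
  expect_true(st$beached)
  expect_equal(st$lon, 29.5)
})

test_that("a zero velocity field is a fixed point of the integrator", {
  ser <- uniform_flow_series(0, 0)
  st <- rk4_step(30, -50, 0, 6, ser)
  expect_equal(c(st$lon, st$lat), c(30, -50))
})

test_that("solid-body orbits close and the scheme converges at order four", {
  gv <- gen_velocity_series("solid_body", lon = seq(25, 35, 0.5),
                            lat = seq(-54, -46, 0.5), time = c(0, 60),
                            center_lon = 30, center_lat = -50,
                            period_days = 30)
  one_period <- function(field, dt_h, period = 30, lat0 = -49) {
    lon <- 30; lat <- lat0; t <- 0
    for (i in seq_len(round(period * 24 / dt_h))) {
      s <- rk4_step(lon, lat, t, dt_h, field, "forward")
      lon <- s$lon; lat <- s$lat; t <- t + dt_h / 24
    }
    sqrt((lon - 30)^2 + (lat - lat0)^2)
  }
  # gridded field: return error dominated by bilinear sampling, still small
  expect_lt(one_period(gv$series, 6), 1e-3)
  # analytic field: pure integrator error, fourth-order dt-halving ratio
  f <- gv$truth$velocity_fun
  e6 <- one_period(f, 6); e3 <- one_period(f, 3)
  expect_lt(e6, 1e-5)
  expect_gt(e6 / e3, 12); expect_lt(e6 / e3, 20)
})

test_that("orbit radius drifts < 0.5% over ten periods of steady rotation", {
  gv <- gen_velocity_series("solid_body", lon = seq(25, 35, 0.5),
                            lat = seq(-54, -46, 0.5), time = c(0, 400),
                            center_lon = 30, center_lat = -50,
                            period_days = 30)
  lon <- 30; lat <- -49; t <- 0
  for (i in seq_len(10 * 30 * 4)) {
    s <- rk4_step(lon, lat, t, 6, gv$series, "forward")
    lon <- s$lon; lat <- s$lat; t <- t + 0.25
  }
  expect_lt(abs(sqrt((lon - 30)^2 + (lat + 50)^2) - 1), 0.005)
})

test_that("backward-then-forward integration re-reaches the seed", {
  gv <- gen_velocity_series("solid_body", lon = seq(25, 35, 0.5),
                            lat = seq(-54, -46, 0.5), time = c(0, 60),
                            center_lon = 30, center_lat = -50,
                            period_days = 30)
  lon <- 31.2; lat <- -49.4; t <- 30
  nst <- 60  # 15 days back
  for (i in seq_len(nst)) {
    s <- rk4_step(lon, lat, t, 6, gv$series, "backward")
    lon <- s$lon; lat <- s$lat; t <- t - 0.25
  }
  for (i in seq_len(nst)) {
    s <- rk4_step(lon, lat, t, 6, gv$series, "forward")
    lon <- s$lon; lat <- s$lat; t <- t + 0.25
  }
  # within 1% of the path length (~ half an orbit circumference)
  path_len <- pi * sqrt(1.2^2 + 0.6^2)
  expect_lt(sqrt((lon - 31.2)^2 + (lat + 49.4)^2), 0.01 * path_len)
})

test_that("source masks answer membership by angular distance and depth", {
  dm <- disk_mask(data.frame(lon = c(30, 30.5), lat = c(-50, -49.5),
                             radius_deg = c(1, 1)))
  expect_true(mask_contains(dm, 30, -50))
  expect_true(mask_contains(dm, 30.5, -49.5))
  expect_false(mask_contains(dm, 35, -50))
  # 1 degree of latitude from center is exactly on the rim
  expect_true(mask_contains(dm, 30, -49.001))
  expect_false(mask_contains(dm, 30, -48.45))
  bm <- shallow_mask(gen_bathymetry(), 500)
  expect_true(mask_contains(bm, 54, -50))    # shelf
  expect_false(mask_contains(bm, 30, -50))   # ridge crest is 1500 m
  expect_false(mask_contains(bm, 40, -50))   # abyssal plain
})

test_that("scavenging fraction follows the exponential closed form", {
  expect_equal(iron_fraction(0, 90), 1)
  expect_equal(iron_fraction(90, 90), exp(-1), tolerance = 1e-15)
  expect_equal(iron_fraction(90 * log(10), 90), 0.1, tolerance = 1e-12)
  expect_true(all(diff(iron_fraction(seq(0, 200, 5), 90)) < 0))
  expect_error(iron_fraction(-1, 90), "non-negative")
  expect_error(iron_fraction(10, 0), "positive")
})

test_that("most recent contact is found backward with distance/speed age", {
  U <- 0.1
  ser <- uniform_flow_series(U, 0)
  masks <- list(disk_mask(data.frame(lon = 30, lat = -50, radius_deg = 1)))
  # seed inside the disk: age zero, full iron fraction
  tr0 <- trace_last_contact(30.2, -50, 80, ser, masks, lookback_days = 60)
  expect_equal(tr0$age, 0)
  expect_equal(tr0$iron_fraction, 1)
  # seed 864 km due east of the disk edge: age 100 days within one step
  phi <- -50 * pi / 180
  lam_edge <- 30 + acos((cos(pi / 180) - sin(phi)^2) / cos(phi)^2) * 180 / pi
  seed_lon <- lam_edge + 864000 / (6371000 * pi / 180 * cos(phi))
  ser_long <- uniform_flow_series(U, 0, time = seq(0, 160, 1))
  tr <- trace_last_contact(seed_lon, -50, 155, ser_long, masks,
                           lookback_days = 150)
  expect_lte(abs(tr$age - 100), 0.25 + 1e-9)   # one integration step
  expect_equal(tr$iron_fraction, exp(-100 / 90), tolerance = 0.01)
  expect_identical(tr$source_label, "ridge_upwelling")
  expect_true(all(diff(tr$path$time) > 0))
  # upstream (west) of the only source in eastward flow: no contact
  trw <- trace_last_contact(27, -50, 80, ser, masks, lookback_days = 60)
  expect_true(is.na(trw$age))
  expect_true(is.na(trw$iron_fraction))
})

test_that("delivery maps pool seasons and respect degenerate inputs", {
  U <- 0.1
  ser <- uniform_flow_series(U, 0, time = seq(0, 80, 1))
  masks <- list(disk_mask(data.frame(lon = 30, lat = -50, radius_deg = 1)))
  lons <- seq(30, 36, 0.5)
  d1 <- seasonal_delivery_map(list(ser), lons, -50, masks, efold = 20,
                              lookback_days = 60)
  d2 <- seasonal_delivery_map(list(ser, ser), lons, -50, masks, efold = 20,
                              lookback_days = 60)
  expect_equal(d1$mean_delivery, d2$mean_delivery)
  expect_equal(d2$n_seeded[1, 1], 2 * d1$n_seeded[1, 1])
  expect_true(all(d1$mean_delivery >= 0 & d1$mean_delivery <= 100,
                  na.rm = TRUE))
  # delivery decreases monotonically downstream of the source
  row <- d1$mean_delivery[, 1]
  east <- which(lons > 31.6)
  expect_true(all(diff(row[east]) < 0, na.rm = TRUE))
  expect_warning(dn <- seasonal_delivery_map(list(ser), lons, -50, list()),
                 "no source masks")
  expect_true(all(is.na(dn$mean_delivery)))
  expect_error(seasonal_delivery_map(list(), lons, -50, masks), "season")
})

test_that("delivery zone thresholding feeds bloom classification", {
  U <- 0.1
  ser <- uniform_flow_series(U, 0, time = seq(0, 80, 1))
  masks <- list(disk_mask(data.frame(lon = 30, lat = -50, radius_deg = 1)))
  dm <- seasonal_delivery_map(list(ser), seq(30, 38, 0.5), seq(-51, -49, 0.5),
                              masks, efold = 20, lookback_days = 60)
  zone <- delivery_zone(dm, 10)
  expect_true(all(zone$z %in% c(0, 1)))
  expect_equal(zone$z[1, which(zone$lat == -50)], 1)   # at the source
  expect_equal(zone$z[length(zone$lon), which(zone$lat == -50)], 0)
})
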