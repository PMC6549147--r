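# Density climatology, optimal interpolation, section extraction, and the
# alongstream dynamic-height-coordinate difference.

test_that("vertical binning is the identity on casts at standard levels", {
  gh <- gen_hydrography(n_profiles = 6, noise_sd = 0, qc_bad_fraction = 0,
                        seed = 3)
  b <- bin_profiles_vertical(gh$hydro)
  expect_equal(nrow(b$sigma), 6)
  direct <- potential_density(
    gh$hydro$temp_C[1:81], gh$hydro$psal[1:81], gh$hydro$pres_dbar[1:81])
  expect_equal(b$sigma[1, ], direct, tolerance = 1e-12)
})

test_that("no extrapolation below a cast's sampled range", {
  gh <- gen_hydrography(n_profiles = 2, noise_sd = 0, qc_bad_fraction = 0,
                        seed = 3)
  hy <- gh$hydro[gh$hydro$pres_dbar <= 1000, ]
  b <- bin_profiles_vertical(hy)
  expect_true(all(is.na(b$sigma[, b$levels > 1000])))
  expect_true(all(is.finite(b$sigma[, b$levels <= 1000])))
  # a one-level cast is dropped with a message
  hy2 <- rbind(hy, transform(hy[1, ], profile_id = "SHORT"))
  expect_message(b2 <- bin_profiles_vertical(hy2), "dropped")
  expect_equal(nrow(b2$sigma), 2)
})

test_that("quality-controlled profiles only enter the climatology", {
  gh <- gen_hydrography(n_profiles = 20, qc_bad_fraction = 0.3, seed = 14)
  b <- bin_profiles_vertical(gh$hydro)
  expect_equal(nrow(b$sigma),
               length(unique(gh$hydro$profile_id[gh$hydro$qc_flag == 1])))
})

test_that("optimal interpolation reproduces constants and linear fields", {
  set.seed(2)
  lon <- runif(300, 20, 40); lat <- runif(300, -54, -46)
  gl <- seq(24, 36, 0.5); ga <- seq(-52, -48, 0.5)
  # constant field -> constant grid
  oi <- optimal_interpolation(lon, lat, rep(27.1, 300), gl, ga, 550)
  expect_equal(as.vector(oi$field), rep(27.1, length(gl) * length(ga)),
               tolerance = 1e-12)
  # single sample -> its value near it, missing beyond the weight floor
  oi1 <- optimal_interpolation(30, -50, 5, gl, ga, scale_km = 100,
                               neff_floor = 0.2)
  at <- oi1$field[which(gl == 30), which(ga == -50), 1]
  expect_equal(at, 5)
  expect_true(any(is.na(oi1$field)))
  # linear (planar) field sampled densely on a regular grid: the symmetric
  # kernel preserves it in the interior to < 1% of the field range
  smp <- expand.grid(lon = seq(20, 40, 0.5), lat = seq(-54, -46, 0.5))
  vals <- 27 + 0.05 * (smp$lon - 30) + 0.1 * (smp$lat + 50)
  oi2 <- optimal_interpolation(smp$lon, smp$lat, vals, gl, ga, scale_km = 200)
  truth <- outer(gl, ga, function(lo, la) 27 + 0.05 * (lo - 30) + 0.1 * (la + 50))
  interior <- abs(oi2$field[, , 1] - truth)[7:19, 3:7]  # lon 27-33, lat -51..-49
  expect_lt(max(interior), 0.01 * diff(range(vals)))
})

test_that("climatology columns are stably stratified after sorting", {
  gh <- gen_hydrography(n_profiles = 300, noise_sd = 0.05, seed = 8,
                        lon_range = c(20, 40))
  clim <- build_density_climatology(gh$hydro,
                                    grid_lon = seq(24, 36, 0.5),
                                    grid_lat = seq(-54, -46, 0.5))
  for (i in seq_along(clim$lon)) for (j in seq_along(clim$lat)) {
    col <- clim$sigma[i, j, ]
    expect_false(is.unsorted(col[is.finite(col)]))
  }
})

test_that("climatology is invariant to profile input order", {
  gh <- gen_hydrography(n_profiles = 100, seed = 10, lon_range = c(24, 36))
  c1 <- build_density_climatology(gh$hydro, grid_lon = seq(26, 34, 0.5),
                                  grid_lat = seq(-53, -47, 0.5))
  set.seed(1)
  shuffled <- gh$hydro[sample(nrow(gh$hydro)), ]
  c2 <- build_density_climatology(shuffled, grid_lon = seq(26, 34, 0.5),
                                  grid_lat = seq(-53, -47, 0.5))
  expect_equal(c1$sigma, c2$sigma, tolerance = 1e-12)
})

test_that("section extraction matches grid columns and interpolates between", {
  gh <- gen_hydrography(n_profiles = 500, noise_sd = 0, seed = 4,
                        lon_range = c(20, 40))
  clim <- build_density_climatology(gh$hydro, grid_lon = seq(24, 36, 0.5),
                                    grid_lat = seq(-55, -45, 0.5))
  s28 <- extract_section(clim, 28)
  i28 <- which(clim$lon == 28)
  jj <- match(s28$lat, clim$lat)
  expect_equal(s28$sigma, clim$sigma[i28, jj, ], tolerance = 1e-12)
  # midway between columns: mean of the two
  smid <- extract_section(clim, 28.25)
  i2 <- which(clim$lon == 28.5)
  expect_equal(smid$sigma,
               (clim$sigma[i28, jj, ] + clim$sigma[i2, jj, ]) / 2,
               tolerance = 1e-12)
  expect_error(extract_section(clim, 60), "outside")
})

test_that("dh coordinate is an affine relabeling when dh is linear in lat", {
  gh <- gen_hydrography(tilt = 0.2, n_profiles = 5, noise_sd = 0, seed = 5)
  sec <- analytic_section(gh$truth, 28)
  dh <- gh$truth$dh_fun(sec$lat, 28)
  # target the dh values of the section latitudes themselves: identity
  out <- to_dh_coordinate(sec, dh, dh_axis = dh)
  expect_equal(out$sigma, sec$sigma, tolerance = 1e-10)
})

test_that("alongstream difference recovers the prescribed tilt and is antisymmetric", {
  gh <- gen_hydrography(tilt = 0.2, n_profiles = 5, noise_sd = 0, seed = 5)
  se <- analytic_section(gh$truth, 38)
  sw <- analytic_section(gh$truth, 28)
  dh_e <- gh$truth$dh_fun(se$lat, 38); dh_w <- gh$truth$dh_fun(sw$lat, 28)
  sector_lat <- seq(-55, -47, 0.5)
  sector_dh <- gh$truth$dh_fun(sector_lat, 33)
  ds <- alongstream_delta_sigma(se, sw, dh_e, dh_w, sector_lat, sector_dh)
  k750 <- which(ds$levels == 750)
  expect_equal(mean(ds$delta_sigma[, k750]), 0.2, tolerance = 1e-6)
  # swapping the sections negates the difference exactly
  ds2 <- alongstream_delta_sigma(sw, se, dh_w, dh_e, sector_lat, sector_dh)
  expect_equal(ds2$delta_sigma, -ds$delta_sigma, tolerance = 1e-12)
  # pseudo-latitude mapping is monotone over the used range
  expect_false(is.unsorted(ds$pseudo_lat))
})

test_that("a meandering front with no water-mass change yields no alongstream signal", {
  # front displaced north downstream; fixed-latitude comparison sees a large
  # spurious signal, the dynamic-height coordinate removes it
  gh <- gen_hydrography(tilt = 0, meander_deg = 4, n_profiles = 5,
                        noise_sd = 0, seed = 6)
  se <- analytic_section(gh$truth, 38)
  sw <- analytic_section(gh$truth, 28)
  naive <- max(abs(se$sigma - sw$sigma))
  expect_gt(naive, 0.04)
  dh_e <- gh$truth$dh_fun(se$lat, 38); dh_w <- gh$truth$dh_fun(sw$lat, 28)
  sector_lat <- seq(-55, -47, 0.5)
  sector_dh <- gh$truth$dh_fun(sector_lat, 33)
  ds <- alongstream_delta_sigma(se, sw, dh_e, dh_w, sector_lat, sector_dh)
  expect_lt(max(abs(ds$delta_sigma), na.rm = TRUE), 1e-6)
})

test_that("non-monotone dh triggers the monotone-envelope restriction", {
  gh <- gen_hydrography(tilt = 0.2, n_profiles = 5, noise_sd = 0, seed = 5)
  sec <- analytic_section(gh$truth, 28)
  dh <- gh$truth$dh_fun(sec$lat, 28)
  dh[5] <- dh[7]   # local inversion
  out <- to_dh_coordinate(sec, dh)
  expect_true(length(out$excluded_lat) >= 1)
  expect_true(all(is.finite(out$sigma[, 10])))
})

test_that("full-chain alongstream contrast matches the generator truth", {
  gh <- gen_hydrography(tilt = 0.2, n_profiles = 1200, noise_sd = 0.01,
                        seed = 15)
  clim <- build_density_climatology(gh$hydro)
  ds <- delta_sigma_between(clim, gh$dh, 28, 38)
  k750 <- which(ds$levels == 750)
  got <- mean(ds$delta_sigma[, k750], na.rm = TRUE)
  expect_equal(got, 0.2, tolerance = 0.15)
})
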