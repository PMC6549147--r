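# Shared fixture builders; everything generated in code at test time.

# profile with a prescribed potential-density structure at fixed salinity
make_sigma_profile <- function(depths, sigma, fluo = rep(100, length(depths)),
                               day_flag = TRUE, psal = 34.2,
                               time = as.POSIXct("2015-01-10 12:00:00", tz = "UTC"),
                               lat = -50, lon = 30) {
  temp <- ventbloom:::invert_sigma_to_temp(sigma, psal, depths)
  ventbloom:::new_profile("TESTFLT", 1L, time, lat, lon, day_flag,
                          depths, temp, rep(psal, length(depths)),
                          fluo, rep(0.001, length(depths)))
}

# spatially uniform steady flow as a gridded series
uniform_flow_series <- function(u0, v0, lon = seq(20, 46, 1),
                                lat = seq(-56, -44, 1), time = seq(0, 80, 1)) {
  dm <- c(length(lon), length(lat), length(time))
  velocity_series(lon, lat, time, array(u0, dm), array(v0, dm))
}

# processed-profile rows with given times and integrated chl, for phenology
proc_rows <- function(times, int_chl = 50, lat = -50, lon = 30,
                      float_id = "F1") {
  data.frame(float_id = float_id, cycle = seq_along(times),
             time = as.POSIXct(times, tz = "UTC"),
             lat = lat, lon = lon, day_flag = TRUE,
             mld_m = 80, zeu_m = 40, int_chl_mg_m2 = int_chl,
             integration_depth_m = 80, flag = "ok",
             stringsAsFactors = FALSE)
}

# analytic meridional density sections from a hydrography-generator truth
analytic_section <- function(truth, lon, lats = seq(-55, -47, by = 0.5),
                             levels = seq(0, 2000, by = 25)) {
  sig <- outer(lats, levels, function(la, P) truth$sigma_fun(P, la, lon))
  structure(list(lon = lon, lat = lats, levels = levels, sigma = sig),
            class = "vb_section")
}
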