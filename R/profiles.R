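# Float-profile processing: quenching correction, fluorescence calibration,
# mixed-layer and euphotic depths, depth-integrated chlorophyll.

#' Fluorescence calibration specification
#'
#' @param dark sensor dark counts.
#' @param slope scale factor, mg m^-3 per count.
#' @param f490 regional radiometric correction factor applied after the
#'   factory calibration; the adopted conservative value 0.3 implies the
#'   factory calibration overestimates chlorophyll by a factor 1/0.3 = 3.3.
#' @return a \code{vb_calibration} list.
#' @export
calibration_spec <- function(dark = 50, slope = 0.007, f490 = 0.3) {
  if (slope <= 0) stop("calibration slope must be positive")
  if (f490 <= 0 || f490 > 1) stop("f490 must lie in (0, 1]")
  structure(list(dark = dark, slope = slope, f490 = f490),
            class = "vb_calibration")
}

#' Mixed layer depth by density threshold
#'
#' Shallowest depth at which potential density exceeds its value at the
#' reference depth by \code{threshold}, located by linear interpolation
#' between the bracketing sampled levels (grid-resolution independent).
#' Pressure is treated as depth in meters at these near-surface scales.
#'
#' @param profile a \code{vb_profile}.
#' @param threshold density excess, kg m^-3 (default 0.03).
#' @param ref_depth reference depth, m (default 10).
#' @return list: \code{mld} (m), \code{flag} one of \code{"ok"},
#'   \code{"never_exceeded"} (returns deepest sampled depth),
#'   \code{"shallow_reference"} (shallowest level in 10-15 m used as
#'   reference), \code{"undefined"} (no usable reference level).
#' @export
compute_mld <- function(profile, threshold = 0.03, ref_depth = 10) {
  z <- profile$pres
  sigma <- suppressWarnings(
    potential_density(profile$temp, profile$psal, profile$pres))
  ok <- is.finite(sigma) & is.finite(z)
  z <- z[ok]; sigma <- sigma[ok]
  if (length(z) < 2)
    return(list(mld = NA_real_, flag = "undefined"))
  flag <- "ok"
  if (min(z) <= ref_depth) {
    sig_ref <- stats::approx(z, sigma, ref_depth)$y
  } else if (min(z) <= ref_depth + 5) {
    sig_ref <- sigma[1]
    flag <- "shallow_reference"
  } else {
    return(list(mld = NA_real_, flag = "undefined"))
  }
  target <- sig_ref + threshold
  below <- which(z >= ref_depth & sigma > target)
  if (!length(below))
    return(list(mld = max(z), flag = "never_exceeded"))
  i <- below[1]
  if (i == 1) return(list(mld = z[1], flag = flag))
  mld <- z[i - 1] + (target - sigma[i - 1]) / (sigma[i] - sigma[i - 1]) *
    (z[i] - z[i - 1])
  list(mld = mld, flag = flag)
}

#' Non-photochemical quenching correction
#'
#' Daytime fluorescence near the surface is suppressed by quenching. For
#' daytime profiles the maximum raw fluorescence at or above the mixed layer
#' depth is extrapolated toward the surface: every level shallower than that
#' maximum is overwritten with it. Night profiles are returned unchanged.
#' Applied on raw counts, before calibration.
#'
#' @param profile a \code{vb_profile}.
#' @param mld mixed layer depth, m.
#' @return corrected fluorescence counts vector.
#' @export
npq_correct <- function(profile, mld) {
  fluo <- profile$fluo
  if (!isTRUE(profile$day_flag)) return(fluo)
  above <- which(profile$pres <= mld & is.finite(fluo))
  if (!length(above)) {
    warning("no levels above the mixed layer; quenching correction skipped")
    return(fluo)
  }
  istar <- above[which.max(fluo[above])]
  fluo[profile$pres < profile$pres[istar]] <- fluo[istar]
  fluo
}

#' Convert fluorescence counts to chlorophyll concentration
#'
#' Applies the factory calibration (dark and slope) and then the regional
#' correction factor: \code{chl = max(fluo - dark, 0) * slope * f490}.
#' Dark-corrected counts below zero clamp to zero concentration.
#'
#' @param fluo fluorescence counts.
#' @param cal a \code{vb_calibration}.
#' @return chlorophyll a, mg m^-3.
#' @export
calibrate_chl <- function(fluo, cal) {
  pmax(fluo - cal$dark, 0) * cal$slope * cal$f490
}

#' Euphotic depth from surface chlorophyll
#'
#' Depth of 1% surface irradiance from the standard case-1-water relation: a
#' cubic in log10 of surface chlorophyll, log10(Zeu) = c0 + c1 x + c2 x^2 +
#' c3 x^3 with x = log10(chl). Default coefficients (1.524, -0.436, -0.0145,
#' 0.0186) are the published clear-sky fit; they give e.g. Zeu = 33.4 m at
#' 1 mg m^-3.
#'
#' @param chl_surface surface chlorophyll, mg m^-3 (> 0).
#' @param coefs polynomial coefficients, low order first.
#' @return euphotic depth, m.
#' @export
euphotic_depth <- function(chl_surface, coefs = c(1.524, -0.436, -0.0145, 0.0186)) {
  if (any(!is.finite(chl_surface)) || any(chl_surface <= 0))
    stop("surface chlorophyll must be positive and finite")
  x <- log10(chl_surface)
  10^(coefs[1] + coefs[2] * x + coefs[3] * x^2 + coefs[4] * x^3)
}

#' Depth-integrated chlorophyll
#'
#' Trapezoidal integral of chlorophyll from the surface to \code{z_max}. The
#' shallowest sampled value is extended to the surface; the value at
#' \code{z_max} is obtained by linear interpolation between the bracketing
#' levels.
#'
#' @param chl chlorophyll, mg m^-3.
#' @param depths sampled depths, m, strictly increasing.
#' @param z_max integration limit, m.
#' @return integrated chlorophyll, mg m^-2, or NA (with warning) when no
#'   level lies above \code{z_max}.
#' @export
integrate_chl <- function(chl, depths, z_max) {
  ok <- is.finite(chl) & is.finite(depths)
  chl <- chl[ok]; depths <- depths[ok]
  if (z_max <= 0) stop("z_max must be positive")
  if (!any(depths <= z_max) || length(depths) < 2) {
    warning("no levels above z_max; integral undefined")
    return(NA_real_)
  }
  if (depths[1] > 0) {       # extend the shallowest value to the surface
    z <- c(0, depths)
    c0 <- c(chl[1], chl)
  } else {
    z <- depths
    c0 <- chl
  }
  if (z_max <= max(depths)) {
    cz <- stats::approx(z, c0, z_max)$y
    keep <- z < z_max
    z <- c(z[keep], z_max); c0 <- c(c0[keep], cz)
  }
  sum(diff(z) * (utils::head(c0, -1) + utils::tail(c0, -1)) / 2)
}

#' Process a float profile series
#'
#' Full per-cast chain: mixed layer depth from density, quenching correction
#' on raw fluorescence (daytime casts), calibration to chlorophyll, euphotic
#' depth from the mean calibrated chlorophyll over the top 10 m, and
#' depth-integrated chlorophyll down to max(MLD, Zeu).
#'
#' @param profiles list of \code{vb_profile}.
#' @param config a \code{vb_config} (calibration, MLD settings, Zeu
#'   coefficients).
#' @return data.frame, one row per cast: \code{float_id, cycle, time, lat,
#'   lon, day_flag, mld_m, zeu_m, int_chl_mg_m2, integration_depth_m, flag}.
#' @export
process_profiles <- function(profiles, config = pipeline_config()) {
  cal <- calibration_spec(config$cal_dark, config$cal_slope, config$f490)
  rows <- lapply(profiles, function(p) {
    m <- compute_mld(p, config$mld_threshold, config$mld_ref_depth)
    out <- data.frame(float_id = p$float_id, cycle = p$cycle, time = p$time,
                      lat = p$lat, lon = p$lon, day_flag = p$day_flag,
                      mld_m = m$mld, zeu_m = NA_real_,
                      int_chl_mg_m2 = NA_real_,
                      integration_depth_m = NA_real_,
                      flag = m$flag, stringsAsFactors = FALSE)
    if (!is.finite(m$mld)) return(out)
    fluo <- npq_correct(p, m$mld)
    chl <- calibrate_chl(fluo, cal)
    top <- p$pres <= 10
    if (!any(top)) top <- seq_len(min(2, length(p$pres)))
    chl_surf <- mean(chl[top])
    zeu <- if (chl_surf > 0)
      euphotic_depth(chl_surf, config$zeu_coefs) else NA_real_
    zint <- max(m$mld, zeu, na.rm = TRUE)
    out$zeu_m <- zeu
    out$integration_depth_m <- zint
    out$int_chl_mg_m2 <- suppressWarnings(integrate_chl(chl, p$pres, zint))
    out
  })
  do.call(rbind, rows)
}
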