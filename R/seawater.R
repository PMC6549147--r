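# Seawater thermodynamics: EOS-80 (UNESCO) density and adiabatic potential
# temperature. Coefficients follow Fofonoff & Millard (1983), Unesco Technical
# Papers in Marine Science 44; unit conventions: T in deg C (IPTS-68 scale
# assumed close enough to ITS-90 for climatological work), S on the practical
# salinity scale, pressure in dbar.

# adiabatic temperature gradient, deg C per dbar
sw_adtg <- function(S, T, P) {
  ds <- S - 35
  (3.5803e-5 + 8.5258e-6 * T - 6.836e-8 * T^2 + 6.6228e-10 * T^3) +
    ds * (1.8932e-6 - 4.2393e-8 * T) +
    P * (1.8741e-8 - 6.7795e-10 * T + 8.733e-12 * T^2 - 5.4481e-14 * T^3) +
    P * ds * (-1.1351e-10 + 2.7759e-12 * T) +
    P^2 * (-4.6206e-13 + 1.8676e-14 * T - 2.1687e-16 * T^2)
}

#' Potential temperature of seawater
#'
#' Temperature a water parcel would have if moved adiabatically from pressure
#' \code{P} to reference pressure \code{Pref}, computed by the classical
#' Runge-Kutta integration of the adiabatic lapse rate.
#'
#' @param S practical salinity.
#' @param T in-situ temperature, deg C.
#' @param P pressure, dbar.
#' @param Pref reference pressure, dbar (default 0, the surface).
#' @return potential temperature, deg C; vectorized over all arguments.
#' @examples
#' sw_ptmp(40, 40, 10000)  # Unesco 44 check value 36.89073
#' @export
sw_ptmp <- function(S, T, P, Pref = 0) {
  dP <- Pref - P
  dth <- dP * sw_adtg(S, T, P)
  th <- T + 0.5 * dth
  q <- dth
  dth <- dP * sw_adtg(S, th, P + 0.5 * dP)
  th <- th + (1 - 1 / sqrt(2)) * (dth - q)
  q <- (2 - sqrt(2)) * dth + (-2 + 3 / sqrt(2)) * q
  dth <- dP * sw_adtg(S, th, P + 0.5 * dP)
  th <- th + (1 + 1 / sqrt(2)) * (dth - q)
  q <- (2 + sqrt(2)) * dth + (-2 - 3 / sqrt(2)) * q
  dth <- dP * sw_adtg(S, th, P + dP)
  th + (dth - 2 * q) / 6
}

# density of pure/sea water at one standard atmosphere (Millero & Poisson 1981)
sw_dens0 <- function(S, T) {
  rw <- 999.842594 + 6.793952e-2 * T - 9.095290e-3 * T^2 +
    1.001685e-4 * T^3 - 1.120083e-6 * T^4 + 6.536332e-9 * T^5
  A <- 8.24493e-1 - 4.0899e-3 * T + 7.6438e-5 * T^2 -
    8.2467e-7 * T^3 + 5.3875e-9 * T^4
  B <- -5.72466e-3 + 1.0227e-4 * T - 1.6546e-6 * T^2
  C <- 4.8314e-4
  rw + A * S + B * S^1.5 + C * S^2
}

# secant bulk modulus, P in bar
sw_seck <- function(S, T, Pb) {
  KW <- 19652.21 + 148.4206 * T - 2.327105 * T^2 +
    1.360477e-2 * T^3 - 5.155288e-5 * T^4
  K0 <- KW +
    S * (54.6746 - 0.603459 * T + 1.09987e-2 * T^2 - 6.1670e-5 * T^3) +
    S^1.5 * (7.944e-2 + 1.6483e-2 * T - 5.3009e-4 * T^2)
  A <- 3.239908 + 1.43713e-3 * T + 1.16092e-4 * T^2 - 5.77905e-7 * T^3 +
    S * (2.2838e-3 - 1.0981e-5 * T - 1.6078e-6 * T^2) + 1.91075e-4 * S^1.5
  B <- 8.50935e-5 - 6.12293e-6 * T + 5.2787e-8 * T^2 +
    S * (-9.9348e-7 + 2.0816e-8 * T + 9.1697e-10 * T^2)
  K0 + A * Pb + B * Pb^2
}

#' In-situ density of seawater (EOS-80)
#'
#' @inheritParams sw_ptmp
#' @return density, kg m^-3.
#' @examples
#' sw_dens(35, 5, 0)      # 1027.67547 (Unesco 44 check value)
#' sw_dens(35, 25, 10000) # 1062.53817
#' @export
sw_dens <- function(S, T, P) {
  Pb <- P / 10  # dbar -> bar
  sw_dens0(S, T) / (1 - Pb / sw_seck(S, T, Pb))
}

#' Potential density anomaly referenced to the surface
#'
#' sigma-0 = rho(S, theta(S, T, P, 0), 0) - 1000, the density a parcel would
#' have if brought adiabatically to the surface. Inputs outside plausible
#' oceanic ranges (T in -2.5..40 deg C, S in 2..42) are rejected as NA and
#' counted in a warning, mirroring level-wise quality control.
#'
#' @param temp in-situ temperature, deg C.
#' @param psal practical salinity.
#' @param pres pressure, dbar.
#' @param lat,lon nominal position, degrees (sigma-0 is referenced to the
#'   surface and does not depend on them; accepted for interface symmetry).
#' @return potential density anomaly sigma-0, kg m^-3.
#' @export
potential_density <- function(temp, psal, pres, lat = NULL, lon = NULL) {
  bad <- !is.finite(temp) | !is.finite(psal) | !is.finite(pres) |
    temp < -2.5 | temp > 40 | psal < 2 | psal > 42 | pres < -1.5
  if (any(bad)) {
    warning(sprintf("%d level(s) outside plausible T/S/P range rejected", sum(bad)))
    temp[bad] <- NA_real_
  }
  theta <- sw_ptmp(psal, temp, pres, 0)
  sw_dens(psal, theta, 0) - 1000
}
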