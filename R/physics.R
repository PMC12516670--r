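#' Physical constants for vapor-equilibrium calculations
#'
#' Bundles the constants used by the Kelvin-equation conversions between soil
#' water potential and equilibrium relative humidity, and the Magnus
#' saturation-vapor-pressure parameterization (Sonntag coefficients over a
#' water surface) used to convert VPD to atmospheric relative humidity.
#'
#' @param Mw Molecular weight of water, kg mol^-1.
#' @param R Universal gas constant, J K^-1 mol^-1.
#' @param rho_w Density of liquid water, kg m^-3.
#' @param magnus_a Saturation-pressure coefficient, hPa.
#' @param magnus_b Dimensionless Magnus coefficient.
#' @param magnus_c Magnus temperature coefficient, degrees C.
#'
#' @return An object of class `sva_constants`: a named list of the six
#'   constants.
#' @examples
#' cst <- sva_constants()
#' rh_from_psi(-3.02e7, 293.15, cst)
#' @export
sva_constants <- function(Mw = 0.018, R = 8.31, rho_w = 1000,
                          magnus_a = 6.112, magnus_b = 17.62,
                          magnus_c = 243.12) {
  vals <- c(Mw = Mw, R = R, rho_w = rho_w, magnus_a = magnus_a,
            magnus_b = magnus_b, magnus_c = magnus_c)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all physical constants must be finite and strictly positive")
  }
  structure(as.list(vals), class = "sva_constants")
}

#' @export
print.sva_constants <- function(x, ...) {
  cat("Physical constants (Kelvin + Magnus):\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Equilibrium relative humidity from water potential (Kelvin equation)
#'
#' RH = exp(Mw * psi / (rho_w * R * T)). Water potential follows the suction
#' sign convention: psi <= 0, with psi = 0 at saturation (RH = 1).
#'
#' @param psi Water potential in Pa, <= 0. Vectorized.
#' @param T Absolute temperature in K, > 0.
#' @param constants A [sva_constants()] object.
#' @return Relative humidity as a fraction in (0, 1].
#' @seealso [psi_from_rh()] for the inverse.
#' @export
rh_from_psi <- function(psi, T, constants = sva_constants()) {
  if (any(psi > 0, na.rm = TRUE)) stop("psi must be <= 0 (suction convention)")
  if (any(T <= 0, na.rm = TRUE)) stop("T must be positive (Kelvin)")
  exp(constants$Mw * psi / (constants$rho_w * constants$R * T))
}

#' Water potential from equilibrium relative humidity (inverse Kelvin)
#'
#' psi = (rho_w * R * T / Mw) * ln(RH); the exact inverse of [rh_from_psi()].
#'
#' @param rh Relative humidity as fraction in (0, 1]. Vectorized.
#' @param T Absolute temperature in K, > 0.
#' @param constants A [sva_constants()] object.
#' @return Water potential in Pa (<= 0; 0 at rh = 1).
#' @examples
#' # ~ -302,000 hPa for 80% RH at 20 degrees C
#' psi_from_rh(0.80, 293.15) / 100
#' @export
psi_from_rh <- function(rh, T, constants = sva_constants()) {
  if (any(rh <= 0 | rh > 1, na.rm = TRUE)) stop("rh must lie in (0, 1]")
  if (any(T <= 0, na.rm = TRUE)) stop("T must be positive (Kelvin)")
  constants$rho_w * constants$R * T / constants$Mw * log(rh)
}

#' Saturation vapor pressure (Magnus form, Sonntag coefficients)
#'
#' @param Ta Air temperature in degrees C.
#' @param constants A [sva_constants()] object.
#' @return Saturation vapor pressure over a water surface, kPa.
#' @export
esat_magnus <- function(Ta, constants = sva_constants()) {
  if (any(Ta <= -constants$magnus_c, na.rm = TRUE)) {
    stop("Ta must exceed -magnus_c (Magnus form singular)")
  }
  # magnus_a is in hPa; return kPa to match FLUXNET VPD units
  constants$magnus_a * exp(constants$magnus_b * Ta / (constants$magnus_c + Ta)) / 10
}

#' Atmospheric relative humidity from VPD and air temperature
#'
#' RHa = 100 * (1 - VPD / esat(Ta)), clipped to [0, 100]. The clip absorbs
#' occasional sensor-level VPD slightly above saturation.
#'
#' @param vpd Vapor pressure deficit, kPa, >= 0. Vectorized.
#' @param Ta Air temperature, degrees C.
#' @param constants A [sva_constants()] object.
#' @return Atmospheric relative humidity in percent, in [0, 100].
#' @export
rha_from_vpd <- function(vpd, Ta, constants = sva_constants()) {
  if (any(vpd < 0, na.rm = TRUE)) stop("vpd must be >= 0")
  rha <- 100 * (1 - vpd / esat_magnus(Ta, constants))
  pmin(pmax(rha, 0), 100)
}
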