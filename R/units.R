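#' Unit conversions and the Hagen-Poiseuille vessel resistance
#'
#' All internal computation is carried out in CGS units (cm, poise, dyn/cm^2,
#' cm^3/s). Conversions to clinical units (mmHg, mL/min) are applied only at
#' the boundaries of the package.
#'
#' @name units
NULL

#' @rdname units
#' @export
MMHG_PER_DYN_CM2 <- 1 / 1333.22

#' @rdname units
#' @export
DYN_CM2_PER_MMHG <- 1333.22

#' Convert pressures between mmHg and dyn/cm^2
#'
#' @param p numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @examples
#' cgs_to_mmhg(mmhg_to_cgs(74)) # 74
#' @export
mmhg_to_cgs <- function(p) p * DYN_CM2_PER_MMHG

#' @rdname mmhg_to_cgs
#' @export
cgs_to_mmhg <- function(p) p * MMHG_PER_DYN_CM2

#' Convert a volumetric flow from cm^3/s to mL/min
#'
#' @param q numeric vector, cm^3/s.
#' @return numeric vector, mL/min.
#' @export
flow_to_ml_min <- function(q) q * 60

#' Hydraulic resistance of a cylindrical vessel
#'
#' Poiseuille resistance \eqn{R_v = 8 L \mu / (\pi r^4)} so that the flow
#' through the vessel is \eqn{Q = \Delta P / R_v}, the hydraulic analogue of
#' Ohm's law.
#'
#' @param length vessel length in cm (> 0).
#' @param radius inner radius in cm (> 0).
#' @param viscosity dynamic viscosity in poise (> 0); blood at the package
#'   default is 0.035 poise (3.5 cP).
#' @return resistance in dyn s cm^-5.
#' @examples
#' vessel_resistance(1, 0.1, 0.035) # ~891.27
#' @export
vessel_resistance <- function(length, radius, viscosity = 0.035) {
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("invalid vessel geometry: length must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop("invalid vessel geometry: radius must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(viscosity)) || any(viscosity <= 0)) {
    stop("invalid vessel geometry: viscosity must be finite and > 0", call. = FALSE)
  }
  8 * length * viscosity / (pi * radius^4)
}
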