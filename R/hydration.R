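#' Hydration parameters for a porous surface model
#'
#' A porous ceramic surface under prescribed suction exposes bacteria to a
#' controlled water matric potential; the suction is set by the height of the
#' liquid column between surface and medium reservoir.
#'
#' @param h Liquid column height in metres (>= 0).
#' @param rho Water density in kg/m^3 (default 998, room temperature).
#' @param g Gravitational acceleration in m/s^2 (default 9.81).
#' @return List of class `hydration_params`.
#' @export
hydration_params <- function(h, rho = 998, g = 9.81) {
  if (!is.numeric(rho) || rho <= 0) stop("rho must be > 0")
  if (!is.numeric(g) || g <= 0) stop("g must be > 0")
  if (!is.numeric(h) || any(h < 0)) stop("h must be >= 0")
  structure(list(rho = rho, g = g, h = h), class = "hydration_params")
}

#' Water matric potential from liquid column height
#'
#' Computes `psi_m = rho * g * h`, reported as a negative potential in kPa
#' (suction convention: lower values mean drier conditions and thinner, less
#' connected liquid films).
#'
#' @param p A [hydration_params] (or a column height in metres, for
#'   convenience).
#' @return Matric potential in kPa (<= 0).
#' @export
matric_potential <- function(p) {
  if (!inherits(p, "hydration_params")) p <- hydration_params(p)
  -(p$rho * p$g * p$h) / 1000
}

#' Liquid column height producing a target matric potential
#'
#' Inverse of [matric_potential]: `h = |psi| * 1000 / (rho * g)`.
#'
#' @param psi_kpa Target matric potential in kPa (<= 0).
#' @param rho Water density in kg/m^3.
#' @param g Gravitational acceleration in m/s^2.
#' @return Column height in metres; round-trips through [matric_potential].
#' @export
column_height_for_potential <- function(psi_kpa, rho = 998, g = 9.81) {
  if (any(psi_kpa > 0)) stop("psi_kpa must be <= 0 (suction convention)")
  abs(psi_kpa) * 1000 / (rho * g)
}
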