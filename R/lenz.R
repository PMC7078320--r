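#' Lenz elastic screening half-angle
#'
#' \eqn{\theta_0 = \lambda / (2\pi R)} with screening radius
#' \eqn{R = a_H Z^{-1/3}} (Bohr radius \eqn{a_H} = 0.0529 nm).
#'
#' @param Z Atomic number (>= 1). Vectorized.
#' @param beam An [beam_condition()] or an energy in keV.
#' @return Screening half-angle in mrad.
#' @examples
#' lenz_screening_angle(6, 30)  # ~ 38 mrad for carbon at 30 keV
#' @export
lenz_screening_angle <- function(Z, beam) {
  if (any(Z < 1)) abort("Atomic number must be >= 1.")
  beam <- as_beam(beam)
  lambda_nm <- beam$wavelength_pm * 1e-3
  R <- .const$a_H * Z^(-1 / 3)
  lambda_nm / (2 * pi * R) * 1e3
}

#' Inelastic characteristic half-angle
#'
#' \eqn{\theta_E = \Delta E / (2 E)} with the mean energy loss
#' `delta_e_ev` (default 20 eV).
#'
#' @inheritParams lenz_screening_angle
#' @param delta_e_ev Mean energy loss per inelastic event, eV.
#' @return Characteristic half-angle in mrad.
#' @export
lenz_theta_e <- function(beam, delta_e_ev = 20) {
  beam <- as_beam(beam)
  delta_e_ev / (2 * beam$energy_kev * 1e3) * 1e3
}

# shared prefactor lambda^4/(4 pi^4 aH^2) [nm^2], optionally gamma^2-corrected
lenz_prefactor <- function(beam, relativistic = FALSE) {
  beam <- as_beam(beam)
  lambda_nm <- beam$wavelength_pm * 1e-3
  g2 <- if (relativistic) beam$gamma^2 else 1
  lambda_nm^4 * g2 / (4 * pi^4 * .const$a_H^2)
}

#' Lenz differential scattering cross sections
#'
#' Small-angle Lenz model. Elastic kernel
#' \eqn{d\sigma/d\Omega = \lambda^4 Z^2 / (4\pi^4 a_H^2) \cdot
#' 1/(\theta^2+\theta_0^2)^2}; inelastic kernel
#' \eqn{\lambda^4 Z / (4\pi^4 a_H^2) \cdot
#' [1 - \theta_0^4/(\theta^2+\theta_0^2)^2] / (\theta^2+\theta_E^2)^2}.
#' Angles are taken in radians inside the formulas; the `relativistic`
#' option applies the standard \eqn{\gamma^2} prefactor correction.
#'
#' @param Z Atomic number.
#' @param beam Beam condition or energy in keV.
#' @param theta_mrad Scattering half-angle(s), mrad (>= 0).
#' @param channel `"elastic"`, `"inelastic"` or `"both"`.
#' @param delta_e_ev Mean inelastic energy loss, eV.
#' @param relativistic Apply the gamma^2 prefactor (default `FALSE`, the
#'   classical small-angle form).
#' @return Differential cross section, nm^2/sr.
#' @examples
#' elastic_dcs(6, 30, 30)
#' @export
lenz_dcs <- function(Z, beam, theta_mrad,
                     channel = c("both", "elastic", "inelastic"),
                     delta_e_ev = 20, relativistic = FALSE) {
  channel <- match.arg(channel)
  if (any(theta_mrad < 0)) abort("`theta_mrad` must be >= 0.")
  if (any(Z < 1)) abort("Atomic number must be >= 1.")
  beam <- as_beam(beam)
  th <- theta_mrad * 1e-3
  th0 <- lenz_screening_angle(Z, beam) * 1e-3
  pref <- lenz_prefactor(beam, relativistic)
  el <- pref * Z^2 / (th^2 + th0^2)^2
  if (channel == "elastic") return(el)
  thE <- lenz_theta_e(beam, delta_e_ev) * 1e-3
  inel <- pref * Z * (1 - th0^4 / (th^2 + th0^2)^2) / (th^2 + thE^2)^2
  if (channel == "inelastic") inel else el + inel
}

#' @rdname lenz_dcs
#' @export
elastic_dcs <- function(Z, beam, theta_mrad, relativistic = FALSE) {
  lenz_dcs(Z, beam, theta_mrad, channel = "elastic", relativistic = relativistic)
}

#' Partial scattering cross section into an angular annulus
#'
#' Small-angle integral \eqn{\sigma(\theta_1,\theta_2) = \int d\sigma/d\Omega
#' \, 2\pi\theta \, d\theta}. The elastic channel has the closed form
#' \eqn{\sigma_{el} = \lambda^4 Z^2/(4\pi^3 a_H^2)\,[1/(\theta_1^2+\theta_0^2)
#' - 1/(\theta_2^2+\theta_0^2)]}; the inelastic channel is integrated by
#' adaptive quadrature of the Lenz inelastic kernel.
#'
#' @inheritParams lenz_dcs
#' @param theta1_mrad,theta2_mrad Annulus bounds in mrad, `0 <= theta1 <= theta2`.
#' @return Cross section in nm^2.
#' @examples
#' partial_cross_section(6, 30, 15, 55, channel = "elastic")
#' @export
partial_cross_section <- function(Z, beam, theta1_mrad, theta2_mrad,
                                  channel = c("both", "elastic", "inelastic"),
                                  delta_e_ev = 20, relativistic = FALSE) {
  channel <- match.arg(channel)
  if (theta1_mrad < 0 || theta2_mrad < theta1_mrad) {
    abort("Annulus bounds must satisfy 0 <= theta1 <= theta2.")
  }
  if (any(Z < 1)) abort("Atomic number must be >= 1.")
  beam <- as_beam(beam)
  if (theta1_mrad == theta2_mrad) return(0)
  t1 <- theta1_mrad * 1e-3
  t2 <- theta2_mrad * 1e-3
  el <- {
    th0 <- lenz_screening_angle(Z, beam) * 1e-3
    pref <- lenz_prefactor(beam, relativistic)
    pref * Z^2 * pi * (1 / (t1^2 + th0^2) - 1 / (t2^2 + th0^2))
  }
  if (channel == "elastic") return(el)
  inel <- integrate(
    function(th) lenz_dcs(Z, beam, th * 1e3, channel = "inelastic",
                          delta_e_ev = delta_e_ev,
                          relativistic = relativistic) * 2 * pi * th,
    t1, t2, rel.tol = 1e-9, abs.tol = 0
  )$value
  if (channel == "inelastic") inel else el + inel
}
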