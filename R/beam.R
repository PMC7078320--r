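#' Relativistic electron wavelength
#'
#' De Broglie wavelength of an electron accelerated through `energy_kev`
#' kilovolts, with the relativistic correction,
#' \eqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / 2 m_0 c^2)}}.
#'
#' @param energy_kev Accelerating energy in keV (> 0). Vectorized.
#' @return Wavelength in picometres.
#' @examples
#' electron_wavelength(30)   # ~ 6.98 pm
#' electron_wavelength(300)  # ~ 1.97 pm
#' @export
electron_wavelength <- function(energy_kev) {
  if (!is.numeric(energy_kev) || any(!is.finite(energy_kev)) || any(energy_kev <= 0)) {
    abort("`energy_kev` must be a positive finite number.")
  }
  V <- energy_kev * 1e3
  with(.const, h / sqrt(2 * me * e * V * (1 + e * V / (2 * me * c^2))) * 1e12)
}

#' Electron beam condition
#'
#' Bundles the accelerating energy with derived relativistic quantities:
#' the de Broglie wavelength and the Lorentz factor.
#'
#' @param energy_kev Accelerating energy in keV (> 0).
#' @return An object of class `lv_beam` with fields `energy_kev`,
#'   `wavelength_pm` and `gamma`.
#' @examples
#' beam_condition(30)
#' @export
beam_condition <- function(energy_kev) {
  wl <- electron_wavelength(energy_kev)
  gamma <- 1 + energy_kev * 1e3 * .const$e / (.const$me * .const$c^2)
  structure(
    list(energy_kev = energy_kev, wavelength_pm = wl, gamma = gamma),
    class = "lv_beam"
  )
}

#' @export
print.lv_beam <- function(x, ...) {
  cat(sprintf("<lv_beam> %g keV (lambda = %.4g pm, gamma = %.4f)\n",
              x$energy_kev, x$wavelength_pm, x$gamma))
  invisible(x)
}

as_beam <- function(x) {
  if (inherits(x, "lv_beam")) x else beam_condition(x)
}

#' Annular dark-field detector geometry
#'
#' @param inner_mrad Inner collection half-angle, mrad (>= 0).
#' @param outer_mrad Outer collection half-angle, mrad (> inner).
#' @return An `lv_detector` object.
#' @examples
#' annular_detector(15, 55)  # the low-angle DF detector geometry
#' @export
annular_detector <- function(inner_mrad = 15, outer_mrad = 55) {
  if (!is.numeric(inner_mrad) || !is.numeric(outer_mrad) ||
      inner_mrad < 0 || outer_mrad <= inner_mrad) {
    abort("Detector angles must satisfy 0 <= inner < outer (mrad).")
  }
  structure(list(inner_mrad = inner_mrad, outer_mrad = outer_mrad),
            class = "lv_detector")
}

#' @export
print.lv_detector <- function(x, ...) {
  cat(sprintf("<lv_detector> annulus %g-%g mrad\n", x$inner_mrad, x$outer_mrad))
  invisible(x)
}
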