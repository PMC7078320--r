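#' Scattering table for a material and beam
#'
#' Precomputes, per "average atom" of the material (atom-fraction-weighted
#' over elements), the Lenz cross sections into the detector annulus and in
#' total (up to the angular cutoff `theta_max`), the corresponding mean free
#' paths, the characteristic angles, and a tabulated angular distribution
#' used by the Monte Carlo sampler.
#'
#' @param material An [material()] or a library material name.
#' @param beam An [beam_condition()] or energy in keV.
#' @param detector An [annular_detector()].
#' @param channel Scattering channels entering the detected signal:
#'   `"both"` (default), `"elastic"` or `"inelastic"`.
#' @param delta_e_ev Mean inelastic energy loss, eV.
#' @param relativistic Apply the gamma^2 prefactor correction.
#' @param theta_max_mrad Angular cutoff for "total" cross sections, mrad
#'   (default pi/2 rad).
#' @return An `lv_scattering_table` with fields `sigma_det`, `sigma_total`
#'   (nm^2/atom), `lambda_det`, `lambda_total` (nm), `theta0_per_element`,
#'   `theta_e` (mrad), and a `lambda_beyond(theta_mrad)` accessor.
#' @examples
#' tab <- build_scattering_table("carbon", 30, annular_detector(15, 55))
#' tab$lambda_det
#' @export
build_scattering_table <- function(material, beam, detector,
                                   channel = c("both", "elastic", "inelastic"),
                                   delta_e_ev = 20, relativistic = FALSE,
                                   theta_max_mrad = 500 * pi) {
  channel <- match.arg(channel)
  material <- as_material(material)
  beam <- as_beam(beam)
  if (!inherits(detector, "lv_detector")) abort("`detector` must be an lv_detector.")
  key <- paste(material$name, material$density,
               paste(material$composition$Z, material$composition$fraction,
                     collapse = ";"),
               beam$energy_kev, detector$inner_mrad, detector$outer_mrad,
               channel, delta_e_ev, relativistic, theta_max_mrad, sep = "|")
  hit <- .table_cache[[key]]
  if (!is.null(hit)) return(hit)
  comp <- material$composition
  n_at <- material_number_density(material)

  sig <- function(t1, t2) {
    sum(comp$fraction * vapply(comp$Z, partial_cross_section, numeric(1),
                               beam = beam, theta1_mrad = t1, theta2_mrad = t2,
                               channel = channel, delta_e_ev = delta_e_ev,
                               relativistic = relativistic))
  }
  sigma_det <- sig(detector$inner_mrad, detector$outer_mrad)
  sigma_total <- sig(0, theta_max_mrad)

  # angular CDF of the combined kernel on a log-spaced grid, for MC sampling
  grid <- c(0, 10^seq(-2, log10(theta_max_mrad), length.out = 1200))
  w <- vapply(grid, function(th) {
    sum(comp$fraction * lenz_dcs(comp$Z, beam, th, channel = channel,
                                 delta_e_ev = delta_e_ev,
                                 relativistic = relativistic)) * 2 * pi * th * 1e-3
  }, numeric(1))
  cdf <- cumsum(c(0, diff(grid * 1e-3) * (head(w, -1) + tail(w, -1)) / 2))
  cdf <- cdf / cdf[length(cdf)]

  out <- structure(list(
    material = material, beam = beam, detector = detector,
    channel = channel, delta_e_ev = delta_e_ev, relativistic = relativistic,
    theta_max_mrad = theta_max_mrad,
    theta0_per_element = setNames(lenz_screening_angle(comp$Z, beam), comp$symbol),
    theta_e = lenz_theta_e(beam, delta_e_ev),
    number_density = n_at,
    sigma_det = sigma_det, sigma_total = sigma_total,
    lambda_det = 1 / (n_at * sigma_det),
    lambda_total = 1 / (n_at * sigma_total),
    angle_grid = grid, angle_cdf = cdf
  ), class = "lv_scattering_table")
  .table_cache[[key]] <- out
  out
}

# session cache: tables are pure functions of their arguments
.table_cache <- new.env(parent = emptyenv())

#' Mean free path for scattering beyond an angle
#'
#' \eqn{\Lambda(\theta) = A_{avg} / (N_A \rho \sigma(\theta, \theta_{max}))};
#' diverges as `theta` approaches the cutoff (nothing scatters beyond it).
#'
#' @param table An `lv_scattering_table`.
#' @param theta_mrad Angle(s), mrad.
#' @return Mean free path in nm (possibly `Inf`).
#' @export
lambda_beyond <- function(table, theta_mrad) {
  stopifnot(inherits(table, "lv_scattering_table"))
  vapply(theta_mrad, function(th) {
    th <- min(th, table$theta_max_mrad)
    s <- sum(table$material$composition$fraction *
               vapply(table$material$composition$Z, partial_cross_section,
                      numeric(1), beam = table$beam, theta1_mrad = th,
                      theta2_mrad = table$theta_max_mrad,
                      channel = table$channel, delta_e_ev = table$delta_e_ev,
                      relativistic = table$relativistic))
    if (s <= 0) Inf else 1 / (table$number_density * s)
  }, numeric(1))
}

# attenuation coefficient 1/Lambda_beyond, 1/nm (0 beyond the cutoff)
mu_beyond <- function(table, theta_mrad) 1 / lambda_beyond(table, theta_mrad)

#' @export
print.lv_scattering_table <- function(x, ...) {
  cat(sprintf(
    "<lv_scattering_table> %s @ %g keV, annulus %g-%g mrad [%s%s]\n",
    x$material$name, x$beam$energy_kev, x$detector$inner_mrad,
    x$detector$outer_mrad, x$channel,
    if (x$relativistic) ", relativistic" else ""))
  cat(sprintf("  sigma_det = %.4g nm^2  sigma_total = %.4g nm^2\n",
              x$sigma_det, x$sigma_total))
  cat(sprintf("  lambda_det = %.4g nm   lambda_total = %.4g nm\n",
              x$lambda_det, x$lambda_total))
  invisible(x)
}

#' @export
tidy.lv_scattering_table <- function(x, ...) {
  comp <- x$material$composition
  tibble(
    element = comp$symbol, Z = comp$Z, fraction = comp$fraction,
    theta0_mrad = unname(x$theta0_per_element),
    sigma_det_nm2 = vapply(comp$Z, partial_cross_section, numeric(1),
                           beam = x$beam, theta1_mrad = x$detector$inner_mrad,
                           theta2_mrad = x$detector$outer_mrad,
                           channel = x$channel, delta_e_ev = x$delta_e_ev,
                           relativistic = x$relativistic)
  )
}

#' @export
glance.lv_scattering_table <- function(x, ...) {
  tibble(
    material = x$material$name, energy_kev = x$beam$energy_kev,
    inner_mrad = x$detector$inner_mrad, outer_mrad = x$detector$outer_mrad,
    channel = x$channel, relativistic = x$relativistic,
    theta_e_mrad = x$theta_e,
    sigma_det_nm2 = x$sigma_det, sigma_total_nm2 = x$sigma_total,
    lambda_det_nm = x$lambda_det, lambda_total_nm = x$lambda_total
  )
}
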