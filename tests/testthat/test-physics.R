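test_that("relativistic electron wavelength matches published values", {
  # frozen from the closed form lambda = h / sqrt(2 m e V (1 + eV/2mc^2)),
  # cross-checked against standard TEM wavelength tables
  expect_equal(electron_wavelength(30), 6.979, tolerance = 0.5e-2)
  expect_equal(electron_wavelength(300), 1.969, tolerance = 0.5e-2)
  expect_equal(electron_wavelength(100), 3.701, tolerance = 0.5e-2)
  # monotone divergence towards zero energy
  e <- c(1000, 300, 100, 30, 10, 1, 0.01)
  expect_true(all(diff(electron_wavelength(e)) > 0))
  expect_error(electron_wavelength(0), "positive")
  expect_error(electron_wavelength(-5), "positive")
})

test_that("beam condition caches derived quantities consistently", {
  b <- beam_condition(30)
  expect_equal(b$wavelength_pm, electron_wavelength(30))
  expect_gt(b$gamma, 1)
  expect_lt(b$gamma, beam_condition(300)$gamma)
})

test_that("Lenz screening angle follows theta0 = lambda / (2 pi aH Z^(-1/3))", {
  # hand evaluation: lambda(30 keV) = 6.979 pm, R = 0.0529 * 6^(-1/3) nm
  lam <- 6.979082e-3
  expect_equal(lenz_screening_angle(6, 30),
               lam / (2 * pi * 0.0529 * 6^(-1 / 3)) * 1e3,
               tolerance = 1e-6)
  expect_equal(lenz_screening_angle(6, 30), 38.15, tolerance = 1e-3)
  # proportional to wavelength
  expect_equal(lenz_screening_angle(6, 300) / lenz_screening_angle(6, 30),
               electron_wavelength(300) / electron_wavelength(30),
               tolerance = 1e-12)
  # grows with Z
  expect_gt(lenz_screening_angle(79, 30), lenz_screening_angle(6, 30))
  expect_error(lenz_screening_angle(0, 30))
})

test_that("elastic differential cross section has the Lenz form", {
  th0 <- lenz_screening_angle(6, 30)
  # finite forward maximum: lambda^4 Z^2 / (4 pi^4 aH^2 theta0^4)
  lam_nm <- electron_wavelength(30) * 1e-3
  peak <- lam_nm^4 * 36 / (4 * pi^4 * 0.0529^2) / (th0 * 1e-3)^4
  expect_equal(elastic_dcs(6, 30, 0), peak, tolerance = 1e-9)
  # value at theta0 is a quarter of the forward value
  expect_equal(elastic_dcs(6, 30, th0), peak / 4, tolerance = 1e-9)
  # frozen spot value, hand-evaluated independently
  expect_equal(elastic_dcs(6, 30, 30), 0.01411428, tolerance = 1e-6)
  # strictly decreasing in angle
  v <- elastic_dcs(6, 30, seq(0, 100, by = 5))
  expect_true(all(diff(v) < 0))
})

test_that("partial cross sections integrate the differential form", {
  expect_equal(partial_cross_section(6, 30, 20, 20), 0)
  # additivity over contiguous annuli
  s_tot <- partial_cross_section(6, 30, 15, 55)
  s_a <- partial_cross_section(6, 30, 15, 30)
  s_b <- partial_cross_section(6, 30, 30, 55)
  expect_equal(s_a + s_b, s_tot, tolerance = 1e-12)
  expect_error(partial_cross_section(6, 30, 55, 15), "theta")
  # channels are additive
  expect_equal(partial_cross_section(6, 30, 15, 55, channel = "both"),
               partial_cross_section(6, 30, 15, 55, channel = "elastic") +
                 partial_cross_section(6, 30, 15, 55, channel = "inelastic"),
               tolerance = 1e-12)
})

test_that("closed forms agree with independent quadrature to 1e-6 relative", {
  for (Z in c(1, 6, 8, 79)) {
    for (E in c(30, 300)) {
      for (b in list(c(15, 55), c(5, 20), c(60, 200))) {
        cf <- partial_cross_section(Z, E, b[1], b[2], channel = "elastic")
        qd <- quad_sigma(Z, E, b[1], b[2], channel = "elastic")
        expect_equal(cf, qd, tolerance = 1e-6)
      }
    }
  }
})

test_that("scattering tables reduce correctly and scale with density", {
  tab_c <- build_scattering_table("carbon", 30, det_default)
  expect_equal(tab_c$sigma_det,
               partial_cross_section(6, 30, 15, 55, channel = "both"),
               tolerance = 1e-12)
  expect_lt(tab_c$sigma_det, tab_c$sigma_total)
  expect_gt(tab_c$lambda_det, 0)
  # doubling density halves mean free paths, cross sections unchanged
  c2 <- material("carbon2", c(C = 1), density = 4.0)
  tab_2 <- build_scattering_table(c2, 30, det_default)
  expect_equal(tab_2$sigma_det, tab_c$sigma_det, tolerance = 1e-12)
  expect_equal(tab_2$lambda_det, tab_c$lambda_det / 2, tolerance = 1e-12)
  # DNA table is finite and positive
  tab_d <- build_scattering_table("dna", 30, det_default)
  expect_true(is.finite(tab_d$sigma_det) && tab_d$sigma_det > 0)
  expect_lt(tab_d$sigma_det, tab_d$sigma_total)
})

test_that("mixture cross sections are atom-fraction linear", {
  mix <- material("co", c(C = 0.5, O = 0.5), density = 1.5)
  tab <- build_scattering_table(mix, 30, det_default)
  s_c <- partial_cross_section(6, 30, 15, 55, channel = "both")
  s_o <- partial_cross_section(8, 30, 15, 55, channel = "both")
  expect_equal(tab$sigma_det, (s_c + s_o) / 2, tolerance = 1e-12)
})

test_that("lambda_beyond is non-decreasing and diverges at the cutoff", {
  tab <- build_scattering_table("carbon", 30, det_default)
  th <- c(0, 5, 15, 55, 200, 800, 1500)
  lb <- lambda_beyond(tab, th)
  expect_true(all(diff(lb) >= 0))
  expect_identical(lambda_beyond(tab, tab$theta_max_mrad), Inf)
})

test_that("low-voltage collection exceeds high-voltage for light elements", {
  for (Z in c(1, 6, 7, 8, 15)) {
    expect_gt(partial_cross_section(Z, 30, 15, 55),
              partial_cross_section(Z, 300, 15, 55))
  }
})

test_that("material library and element plumbing validate inputs", {
  lib <- material_library()
  expect_setequal(names(lib), c("dna", "carbon", "gold"))
  expect_equal(sum(lib$dna$composition$fraction), 1, tolerance = 1e-12)
  expect_error(material("bad", c(C = 0.5), density = 1), "sum to 1")
  expect_error(material("bad", c(C = 1), density = -1), "density")
  expect_error(element_record("X", 0, 1))
  expect_error(annular_detector(55, 15))
})
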