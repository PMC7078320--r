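# shared fixtures; everything here is cheap to build and deterministic

det_default <- annular_detector(15, 55)
as_mat <- function(x) lvstem:::as_material(x)
film_stack <- layer_stack(carbon = 3, label = "film")
sdn_stack <- layer_stack(carbon = 3, dna = 7.4, label = "film+sDN")

# independent trapezoid quadrature of the Lenz kernels, used as the oracle
# against the package's closed forms / integrate() path
quad_sigma <- function(Z, energy_kev, t1_mrad, t2_mrad, channel = "elastic",
                       n = 20001) {
  th <- seq(t1_mrad, t2_mrad, length.out = n) * 1e-3
  f <- lenz_dcs(Z, energy_kev, th * 1e3, channel = channel) * 2 * pi * th
  sum((f[-1] + f[-n]) / 2 * diff(th))
}

# constructed count image: uniform background plus axis-aligned rectangles
make_rect_image <- function(nx = 120, ny = 100, bg = 10, fg = 30,
                            rects = list(), seed = 1, pixel_size = 1) {
  set.seed(seed)
  mu <- matrix(bg, ny, nx)
  for (r in rects) mu[r[1]:r[2], r[3]:r[4]] <- fg
  counts <- matrix(rpois(ny * nx, mu), ny, nx)
  q <- lvstem:::quantize_8bit(counts)
  stem_image(counts, pixel_size = pixel_size, channel = "DF",
             display = q$display, gain = q$gain)
}

# one rendered synthetic image from a template (analytic render path)
render_one <- function(class = "sdn", seed = 1, dose = 200, orientation = 0,
                       probe_fwhm = 1.5, ...) {
  spec <- population_spec(n_images = 1, class_mix = setNames(1, class),
                          dose = dose, seed = seed, probe_fwhm = probe_fwhm)
  tpl <- structure_template(class, orientation = orientation, ...)
  maps <- project_mass_thickness(tpl, spec$raster)
  S <- render_expected_signal(maps, 30, det_default)
  degrade(S, spec$raster$pixel_size, probe_fwhm, dose, rng_seed = seed)
}
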