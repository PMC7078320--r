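test_that("scene geometry resolves materials by priority", {
  scene <- scene_preset("hdn")
  # inside the gold sphere (resting on the film, centered on the hole)
  expect_identical(material_at(scene, 0, 0, 11), "gold")
  # in the hole, above the support, outside the sphere: vacuum
  expect_identical(material_at(scene, 0, -6.9, 3.2), "vacuum")
  # inside the DNA slab
  expect_identical(material_at(scene, 20, 0, 5), "dna")
  # support film and vacuum below it
  expect_identical(material_at(scene, 0, 0, 1), "carbon")
  expect_identical(material_at(scene, 0, 0, -1), "vacuum")
  # above everything
  expect_identical(material_at(scene, 0, 0, 50), "vacuum")
})

test_that("scene descriptions round-trip through the text format", {
  scene <- scene_preset("hdn", orientation_deg = 25)
  f <- tempfile(fileext = ".yaml")
  write_scene(scene, f)
  back <- read_scene(f)
  pts <- cbind(runif(200, -35, 35), runif(200, -25, 25), runif(200, -2, 25))
  expect_identical(material_at(scene, pts[, 1], pts[, 2], pts[, 3]),
                   material_at(back, pts[, 1], pts[, 2], pts[, 3]))
})

test_that("sampled free paths and deflections match the table", {
  tab <- build_scattering_table("carbon", 30, det_default)
  set.seed(101)
  s <- sample_scatter(1e5, tab)
  expect_equal(mean(s$free_path), tab$lambda_total, tolerance = 2e-2)
  # polar angles follow the tabulated kernel CDF (KS test)
  cdf_fun <- approxfun(tab$angle_grid, tab$angle_cdf, yleft = 0, yright = 1)
  ks <- suppressWarnings(ks.test(s$polar_mrad, cdf_fun))
  expect_gt(ks$p.value, 0.01)
  # identical seed reproduces the identical stream
  set.seed(7); a <- sample_scatter(100, tab)
  set.seed(7); b <- sample_scatter(100, tab)
  expect_identical(a, b)
})

test_that("a vacuum scene transmits every electron exactly on axis", {
  empty <- specimen_scene(support_thickness = 1e-12,
                          bounds = c(-5, 5, -5, 5))
  tr <- trace_electron(empty, 0, 0, 30, det_default,
                       mc_config(rng_seed = 3), n = 500)
  expect_true(all(tr$status == "transmitted"))
  expect_true(all(tr$exit_polar_mrad == 0))
})

test_that("MC transmission through a thin film matches the analytic model", {
  scene <- specimen_scene(bounds = c(-5, 5, -5, 5))  # bare 3 nm carbon
  tr <- trace_electron(scene, 0, 0, 30, det_default,
                       mc_config(rng_seed = 11), n = 1e5)
  sm <- attr(tr, "summary")
  s_hat <- sm$detected / sm$n
  s_ref <- df_signal_fraction(film_stack, 30, det_default)
  se <- sqrt(s_ref * (1 - s_ref) / sm$n)
  expect_lt(abs(s_hat - s_ref), 3 * se)
  # electron conservation
  expect_identical(sm$detected + sm$transmitted_outside + sm$backscattered +
                     sm$capped, as.integer(sm$n))
})

test_that("thicker films scatter more electrons beyond the inner angle", {
  frac_beyond <- function(t_nm, seed) {
    sc <- specimen_scene(support_thickness = t_nm, bounds = c(-5, 5, -5, 5))
    tr <- trace_electron(sc, 0, 0, 30, det_default,
                         mc_config(rng_seed = seed), n = 2e4)
    mean(tr$exit_polar_mrad >= 15, na.rm = TRUE)
  }
  expect_gt(frac_beyond(6, 21), frac_beyond(3, 21))
})

test_that("simulated DF images are reproducible and statistically calibrated", {
  scene <- specimen_scene(bounds = c(-20, 20, -20, 20))
  cfg <- mc_config(electrons_per_pixel = 400, rng_seed = 5)
  raster <- image_raster(10, 8, 2)
  img1 <- simulate_df_image(scene, 30, det_default, cfg, raster)
  img2 <- simulate_df_image(scene, 30, det_default, cfg, raster)
  expect_identical(img1$pixels, img2$pixels)
  # uniform film: mean detected count ~ Binomial(npx, S)
  s_ref <- df_signal_fraction(film_stack, 30, det_default)
  n_tot <- 400 * length(img1$pixels)
  se <- sqrt(s_ref * (1 - s_ref) / n_tot)
  expect_lt(abs(mean(img1$pixels) / 400 - s_ref), 3 * se)
  expect_error(simulate_df_image(scene, 30, det_default, cfg,
                                 image_raster(50, 50, 2)), "bounds")
})

test_that("the DNA slab is brighter than bare film in MC images", {
  scene <- scene_preset("sdn")
  cfg <- mc_config(electrons_per_pixel = 300, rng_seed = 9)
  img <- simulate_df_image(scene, 30, det_default, cfg,
                           image_raster(30, 20, 2))
  co <- lvstem:::raster_coords(image_raster(30, 20, 2))
  on_slab <- abs(co$x) < 25 & abs(co$y) < 11
  off_slab <- abs(co$x) > 33 | abs(co$y) > 17
  tt <- t.test(img$pixels[on_slab], img$pixels[off_slab], alternative = "greater")
  expect_lt(tt$p.value, 1e-3)
})

test_that("the nanoparticle center darkens relative to its rim as it grows", {
  sw <- aunp_diameter_sweep(c(8, 16, 32, 64),
                            config = mc_config(electrons_per_pixel = 4000,
                                               rng_seed = 3))
  expect_identical(nrow(sw), 4L)
  # one-sided z-tests: no significant increase of center/rim with diameter
  n_c <- 4000; n_r <- 8 * 4000
  for (i in 1:3) {
    r1 <- sw$center_rim_ratio[i]; r2 <- sw$center_rim_ratio[i + 1]
    se <- sqrt(r1^2 * (1 / (sw$center[i] * n_c) + 1 / (sw$rim[i] * n_r)) +
                 r2^2 * (1 / (sw$center[i + 1] * n_c) + 1 / (sw$rim[i + 1] * n_r)))
    expect_lt(r2 - r1, qnorm(0.99) * se)
  }
  # single diameter gives a single row
  expect_identical(nrow(aunp_diameter_sweep(16,
    config = mc_config(electrons_per_pixel = 100, rng_seed = 1))), 1L)
})

test_that("the SE proxy separates gold from carbon-based materials", {
  scene <- scene_preset("hdn")
  raster <- image_raster(40, 30, 2)
  se <- se_proxy_image(scene, raster, rng_seed = 5)
  co <- lvstem:::raster_coords(raster)
  gold <- sqrt(co$x^2 + co$y^2) < 6
  dna <- abs(co$x) < 25 & abs(co$y) < 11 & sqrt(co$x^2 + co$y^2) > 12
  film <- abs(co$x) > 33
  # gold is far brighter than DNA (by about the configured yield ratio)
  expect_gt(mean(se$pixels[gold]) / mean(se$pixels[dna]), 5)
  # DNA is statistically indistinguishable from the bare film
  wt <- wilcox.test(se$pixels[dna], se$pixels[film])
  expect_gt(wt$p.value, 0.01)
  # zero yields give an all-zero image
  se0 <- se_proxy_image(scene, raster,
                        yields = c(dna = 0, carbon = 0, gold = 0, vacuum = 0),
                        rng_seed = 1)
  expect_true(all(se0$pixels == 0))
})
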