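test_that("ROI contrast implements (I_D - I_B)/I_B exactly", {
  px <- matrix(60, 40, 40)
  px[11:20, 11:20] <- 120
  img <- stem_image(px, 1, display = NULL)
  rp <- roi_pair(c(10, 20, 10, 20), c(25, 35, 25, 35))
  cm <- roi_contrast(img, rp)
  expect_equal(cm$I_D, 120)
  expect_equal(cm$I_B, 60)
  expect_equal(cm$contrast, 1.0)
  # equal intensities give zero
  cm0 <- roi_contrast(img, roi_pair(c(25, 35, 0, 10), c(25, 35, 25, 35)))
  expect_equal(cm0$contrast, 0)
  # stored contrast always equals the recomputed definition
  expect_equal(cm$contrast, (cm$I_D - cm$I_B) / cm$I_B, tolerance = 1e-15)
  expect_error(roi_pair(c(10, 20, 10, 20), c(15, 25, 15, 25)), "disjoint")
  expect_error(roi_contrast(img, roi_pair(c(0, 5, 0, 5), c(38, 45, 0, 5))),
               "outside")
  zero <- stem_image(matrix(0, 10, 10), 1)
  expect_error(roi_contrast(zero, roi_pair(c(0, 3, 0, 3), c(6, 9, 6, 9))),
               "undefined")
})

test_that("measured contrast recovers the generator's ground truth", {
  spec <- population_spec(n_images = 12, seed = 77)
  pop <- generate_population(spec, 30, det_default)
  res <- purrr::map_dfr(seq_len(12), function(i)
    analyze_image(pop$images$df[[i]], detect = FALSE))
  # measured contrasts track the generated multiplicative scales
  expect_gt(cor(res$contrast, pop$truth$contrast_scale), 0.95)
  base <- predict_contrast(sdn_stack, film_stack, 30, det_default)$contrast
  expect_equal(mean(res$contrast / pop$truth$contrast_scale), base,
               tolerance = 0.1)
})

test_that("segmentation finds isolated structures and flags merges", {
  # blank film: nothing to segment
  blank <- make_rect_image(rects = list(), seed = 2)
  expect_identical(nrow(segment_structures(blank)), 0L)
  # three isolated rectangles (mirrors a three-structure field of view)
  img3 <- make_rect_image(rects = list(c(10, 30, 10, 40), c(50, 70, 20, 50),
                                       c(40, 60, 70, 100)), seed = 3)
  seg <- segment_structures(img3)
  expect_identical(nrow(seg), 3L)
  # two abutting rectangles merge into one big component, which is flagged
  img_m <- make_rect_image(rects = list(c(10, 25, 10, 40), c(26, 41, 10, 40),
                                        c(60, 75, 10, 40), c(60, 75, 60, 90),
                                        c(10, 25, 60, 90)), seed = 4)
  tab <- analyze_image(img_m, detect = FALSE)
  expect_identical(nrow(tab), 4L)
  expect_identical(sum(tab$merged_suspect), 1L)
  expect_gt(max(tab$area_nm2), 1.8 * median(tab$area_nm2))
})

test_that("minimum-area rectangle recovers clean rectangles to a pixel", {
  r <- image_raster(192, 160, 0.5)
  # axis-aligned design rectangle
  fp0 <- which(project_mass_thickness(structure_template("sdn"), r)$dna > 0,
               arr.ind = TRUE)
  d0 <- measure_dimensions(fp0, 0.5)
  expect_lt(abs(d0$length - 59.2), 0.51)
  expect_lt(abs(d0$width - 28.5), 0.51)
  # rotated by 30 degrees: dimensions invariant, orientation recovered
  fp30 <- which(project_mass_thickness(
    structure_template("sdn", orientation = 30), r)$dna > 0, arr.ind = TRUE)
  d30 <- measure_dimensions(fp30, 0.5)
  expect_lt(abs(d30$length - 59.2), 0.51)
  expect_lt(abs(d30$width - 28.5), 0.51)
  expect_lt(min(abs(d30$orientation - 30), 180 - abs(d30$orientation - 30)), 2)
  # square footprint: length equals width
  sq <- as.matrix(expand.grid(10:29, 15:34))
  dsq <- measure_dimensions(sq, 1)
  expect_equal(dsq$length, dsq$width)
  # collinear footprint is degenerate
  expect_error(measure_dimensions(cbind(5, 1:30), 1), "egenerate")
})

test_that("automatic ROIs are disjoint and avoid all neighbors", {
  img3 <- make_rect_image(rects = list(c(10, 30, 10, 40), c(50, 70, 20, 50),
                                       c(40, 60, 70, 100)), seed = 5)
  seg <- segment_structures(img3)
  labels <- attr(seg, "labels")
  for (i in seg$id) {
    rp <- auto_roi(seg, i)
    sb <- rp$structure_box; bb <- rp$background_box
    expect_false(lvstem:::boxes_overlap(sb, bb))
    # structure box sits on this footprint (noise pores aside), never on
    # another structure
    in_box <- labels[(sb[1] + 1):sb[2], (sb[3] + 1):sb[4]]
    expect_true(all(in_box %in% c(0L, i)))
    expect_gt(mean(in_box == i), 0.8)
    # background box avoids every footprint
    expect_true(all(labels[(bb[1] + 1):bb[2], (bb[3] + 1):bb[4]] == 0))
  }
  # a footprint too small for a box errors out
  tiny <- make_rect_image(rects = list(c(20, 22, 20, 22)), seed = 6)
  seg_t <- segment_structures(tiny, min_area = 1)
  if (nrow(seg_t) > 0) expect_error(auto_roi(seg_t, 1), "small|background")
})

test_that("ratio normalization closes on its reference set", {
  m <- tibble::tibble(id = 1:5, contrast = c(1.0, 1.1, 0.9, 1.05, 2.0),
                      class = c("sdn", "sdn", "sdn", "sdn", "ddn"))
  # whole-table normalization has mean ratio exactly 1
  r_all <- normalize_ratios(m, "all")
  expect_equal(mean(r_all$ratio), 1, tolerance = 1e-15)
  # explicit reference ids (the four single-layer structures)
  r_ref <- normalize_ratios(m, reference = 1:4)
  expect_equal(r_ref$ratio[5], 2.0 / mean(c(1.0, 1.1, 0.9, 1.05)),
               tolerance = 1e-12)
  # a structure at exactly twice the reference has ratio 2
  m2 <- tibble::tibble(id = 1:3, contrast = c(1, 1, 2))
  expect_equal(normalize_ratios(m2, reference = 1:2)$ratio[3], 2)
  # per-class closure
  r_cls <- normalize_ratios(m, "class")
  expect_equal(mean(r_cls$ratio[r_cls$class == "sdn"]), 1, tolerance = 1e-12)
  expect_error(normalize_ratios(m[0, ], "all"), "Empty")
})

test_that("layer calls follow the nearest-prediction rule", {
  expect_identical(classify_layers(1.02), 1L)
  expect_identical(classify_layers(1.94), 2L)
  expect_identical(classify_layers(1.94, model = "saturating"), 2L)
  # brute-force oracle: nearest of the supplied predictions decides
  preds <- c(1.0, 1.94)
  brute <- function(r) which.min(abs(r - preds))
  for (r in c(1.3, 1.46, 1.48, 1.5, 1.7, 1.94, 2.4)) {
    expect_identical(classify_layers(r, model = "saturating", n_max = 2,
                                     predictions = preds),
                     as.integer(brute(r)))
  }
  # 1.5 sits closer to 1.94 than to 1.0
  expect_identical(classify_layers(1.5, model = "saturating", n_max = 2,
                                   predictions = preds), 2L)
  # exact midpoint ties break toward fewer layers
  expect_identical(classify_layers(1.5, model = "saturating", n_max = 2,
                                   predictions = c(1, 2)), 1L)
  expect_error(classify_layers(-1), "ratio")
})

test_that("line profiles reproduce the printed nshdn and hdn signatures", {
  # constant image gives a constant profile
  flat <- stem_image(matrix(7, 30, 40), 1)
  pr <- line_profile(flat, c(15, 2), c(15, 39))
  expect_true(all(pr$intensity == 7))
  expect_error(line_profile(flat, c(5, 5), c(5, 5)), "Zero-length")

  # nshdn: drop to the film level at the center between two DNA plateaus
  # (profile along the length axis through the structure center)
  img_h <- render_one("nshdn", seed = 8, dose = 1000)
  ctr_row <- (nrow(img_h$pixels) + 1) / 2
  ctr_col <- (ncol(img_h$pixels) + 1) / 2
  prof <- line_profile(img_h, c(ctr_row, ctr_col - 70), c(ctr_row, ctr_col + 70),
                       width_px = 9)
  x <- (prof$position_nm - max(prof$position_nm) / 2)  # nm from center
  bg <- mean(prof$intensity[abs(x) > 32])
  center <- mean(prof$intensity[abs(x) < 2.5])
  plateau <- mean(prof$intensity[abs(x) > 10 & abs(x) < 27])
  expect_gt(plateau, bg * 1.5)
  expect_lt(center, (bg + plateau) / 2)         # dips well below the DNA level
  expect_lt(abs(center - bg) / (plateau - bg), 0.25)  # ... down to ~film level

  # hdn: plateau-peak-plateau with the peak on the nanoparticle
  img_a <- render_one("hdn", seed = 9, dose = 1000)
  prof_a <- line_profile(img_a, c(ctr_row, ctr_col - 70), c(ctr_row, ctr_col + 70),
                         width_px = 9)
  xa <- (prof_a$position_nm - max(prof_a$position_nm) / 2)
  bg_a <- mean(prof_a$intensity[abs(xa) > 32])
  peak <- max(prof_a$intensity[abs(xa) < 9])
  plat_a <- mean(prof_a$intensity[abs(xa) > 12 & abs(xa) < 27])
  expect_gt(plat_a, bg_a)
  expect_gt(peak, plat_a * 1.3)
})

test_that("hole and particle detectors match the generated structures", {
  hits <- purrr::map_dfr(1:6, function(s) {
    spec <- population_spec(n_images = 1, class_mix = c(nshdn = 1),
                            seed = 300 + s)
    pop <- generate_population(spec, 30, det_default)
    analyze_image(pop$images$df[[1]])
  })
  expect_true(all(hits$hole_detected))
  expect_true(all(abs(hits$hole_length - 15.6) <= 1))   # 2 px at 0.5 nm/px
  expect_true(all(abs(hits$hole_width - 14.2) <= 1))
  expect_true(all(!hits$particle_detected))

  parts <- purrr::map_dfr(1:6, function(s) {
    spec <- population_spec(n_images = 1, class_mix = c(hdn = 1),
                            seed = 400 + s)
    pop <- generate_population(spec, 30, det_default)
    analyze_image(pop$images$df[[1]])
  })
  expect_true(all(parts$particle_detected))
  expect_true(all(abs(parts$particle_diameter - 16) <= 2))

  # plain slabs: no hole, no particle
  plains <- purrr::map_dfr(1:6, function(s) {
    spec <- population_spec(n_images = 1, seed = 500 + s)
    pop <- generate_population(spec, 30, det_default)
    analyze_image(pop$images$df[[1]])
  })
  expect_true(all(!plains$hole_detected))
  expect_true(all(!plains$particle_detected))
})

test_that("population statistics summarize per class with population SDs", {
  one <- tibble::tibble(class = "sdn", length = 60, width = 30,
                        contrast = 1, ratio = 1)
  st <- population_stats(one)
  expect_true(all(st$sd == 0))
  m <- tibble::tibble(class = rep(c("sdn", "ddn"), each = 10),
                      length = rnorm(20, 60, 2), width = rnorm(20, 30, 2),
                      contrast = c(rnorm(10, 1, 0.1), rnorm(10, 1.9, 0.1)),
                      ratio = c(rnorm(10, 1, 0.1), rnorm(10, 1.9, 0.1)))
  st2 <- population_stats(m)
  r <- tidyr::pivot_wider(st2[st2$metric == "ratio", c("class", "mean", "sd")],
                          names_from = "class", values_from = c("mean", "sd"))
  # class separation far exceeds the pooled spread
  expect_gt(abs(r$mean_ddn - r$mean_sdn), r$sd_ddn + r$sd_sdn)
  expect_error(population_stats(m[0, ]), "Empty")
})

test_that("the analyzer is deterministic", {
  img <- render_one("nshdn", seed = 12)
  expect_identical(analyze_image(img), analyze_image(img))
})
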