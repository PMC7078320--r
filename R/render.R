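#' Expected DF signal map from mass-thickness maps
#'
#' Applies the layered single-scattering DF model pixel-wise to the local
#' stack (support + DNA + gold thicknesses). This is the fast analytic
#' render path; it shares its physics with [df_signal_fraction()].
#'
#' For `hdn` templates the gold disc is instead rendered at an empirical
#' dark-field level, `aunp_contrast_ratio` times the single-layer DNA
#' contrast above background (default 2, the observed AuNP/DNA intensity
#' relation): at 16 nm of gold the single-scattering model is far outside
#' its validity range and predicts below-film intensity, while the observed
#' particles are bright. Set `aunp_contrast_ratio = NULL` to keep the raw
#' single-scattering value (as the Monte Carlo module does).
#'
#' @param maps Output of [project_mass_thickness()].
#' @param beam,detector Beam and detector.
#' @param channel,model,delta_e_ev,relativistic Physics options as in
#'   [df_signal_fraction()].
#' @param aunp_contrast_ratio Empirical AuNP DF level (x DNA plateau
#'   contrast), or `NULL` for the raw model.
#' @return Matrix of expected detected fractions.
#' @export
render_expected_signal <- function(maps, beam = 30,
                                   detector = annular_detector(15, 55),
                                   channel = "both",
                                   model = c("difference", "collection"),
                                   delta_e_ev = 20, relativistic = FALSE,
                                   aunp_contrast_ratio = 2) {
  model <- match.arg(model)
  tabs <- lapply(c("dna", "gold", "carbon"), build_scattering_table,
                 beam = beam, detector = detector, channel = channel,
                 delta_e_ev = delta_e_ev, relativistic = relativistic)
  names(tabs) <- c("dna", "gold", "carbon")
  if (model == "collection") {
    s_det <- maps$dna / tabs$dna$lambda_det + maps$gold / tabs$gold$lambda_det +
      maps$support / tabs$carbon$lambda_det
    S <- 1 - exp(-s_det)
  } else {
    mu_in <- vapply(tabs, mu_beyond, numeric(1), theta_mrad = detector$inner_mrad)
    mu_out <- vapply(tabs, mu_beyond, numeric(1), theta_mrad = detector$outer_mrad)
    s_in <- maps$dna * mu_in["dna"] + maps$gold * mu_in["gold"] +
      maps$support * mu_in["carbon"]
    s_out <- maps$dna * mu_out["dna"] + maps$gold * mu_out["gold"] +
      maps$support * mu_out["carbon"]
    S <- exp(-s_out) - exp(-s_in)
  }
  if (!is.null(aunp_contrast_ratio) && any(maps$gold > 0)) {
    bg <- df_signal_fraction(layer_stack(carbon = maps$support[1]),
                             beam, detector, channel = channel, model = model,
                             delta_e_ev = delta_e_ev,
                             relativistic = relativistic)
    plateau <- df_signal_fraction(
      layer_stack(carbon = maps$support[1], dna = max(maps$dna[maps$dna > 0], 7.4)),
      beam, detector, channel = channel, model = model,
      delta_e_ev = delta_e_ev, relativistic = relativistic)
    S[maps$gold > 0] <- bg + aunp_contrast_ratio * (plateau - bg)
  }
  S
}

#' Degrade an expected signal map into a recorded image
#'
#' Instrument realism chain: Gaussian probe blur of FWHM `probe_fwhm`,
#' Poisson shot noise at `dose` incident electrons per pixel (pixel counts
#' are Poisson with mean `dose * signal`), and optional linear 8-bit
#' quantization with recorded gain and zero offset. Fully seed-reproducible.
#'
#' @param expected Matrix of expected detected fractions (or any
#'   nonnegative expected rates).
#' @param pixel_size nm per pixel.
#' @param probe_fwhm Probe FWHM, nm (0 disables blur).
#' @param dose Incident electrons per pixel (> 0).
#' @param rng_seed Seed.
#' @param quantize Produce the 8-bit display form (default TRUE).
#' @param channel Image channel tag.
#' @param provenance Extra provenance fields to record.
#' @return An [stem_image()] with counts (and display if `quantize`).
#' @export
degrade <- function(expected, pixel_size = 0.5, probe_fwhm = 1.5, dose = 200,
                    rng_seed = 1, quantize = TRUE, channel = "DF",
                    provenance = list()) {
  if (probe_fwhm < 0) abort("`probe_fwhm` must be >= 0.")
  if (dose <= 0) abort("`dose` must be > 0.")
  blurred <- blur_map(expected, probe_fwhm / pixel_size)
  set.seed(derive_seed(rng_seed, 7L))
  counts <- matrix(rpois(length(blurred), dose * pmax(blurred, 0)),
                   nrow(blurred), ncol(blurred))
  prov <- c(list(kind = "synthetic", seed = rng_seed, dose = dose,
                 probe_fwhm = probe_fwhm, pixel_size = pixel_size), provenance)
  if (quantize) {
    q <- quantize_8bit(counts)
    stem_image(counts, pixel_size, channel, display = q$display,
               gain = q$gain, offset = q$offset, provenance = prov)
  } else {
    stem_image(counts, pixel_size, channel, provenance = prov)
  }
}

# Gaussian blur via EBImage; sigma in pixels
blur_map <- function(m, sigma_px) {
  if (sigma_px <= 1e-9) return(m)
  sigma_px <- sigma_px / 2.354820045  # FWHM -> sd
  out <- EBImage::imageData(EBImage::gblur(m, sigma = sigma_px,
                                           boundary = "replicate"))
  matrix(out, nrow(m), ncol(m))
}

#' Synthetic population specification
#'
#' The study conditions for generated image populations: class mix, size and
#' contrast variability matching the measured population spreads, and the
#' imaging dose.
#'
#' @param n_images Number of images.
#' @param class_mix Named fractions over `sdn`, `ddn`, `nshdn`, `hdn`
#'   (must sum to 1).
#' @param size_cv Coefficient of variation of the lateral dimensions;
#'   length-2 `c(length, width)` or a scalar. Defaults `c(4.1/61.5, 4.0/37.5)`,
#'   the reported survey spreads.
#' @param contrast_cv Multiplicative contrast variability (SD of a unit-mean
#'   scale factor).
#' @param dose Incident electrons per pixel.
#' @param seed Integer master seed.
#' @param raster An [image_raster()] for each image.
#' @param probe_fwhm Probe FWHM, nm.
#' @return An `lv_population_spec`.
#' @export
population_spec <- function(n_images = 110, class_mix = c(sdn = 1),
                            size_cv = c(4.1 / 61.5, 4.0 / 37.5),
                            contrast_cv = 0.15, dose = 200, seed = 1,
                            raster = image_raster(224, 176, 0.5),
                            probe_fwhm = 1.5) {
  if (abs(sum(class_mix) - 1) > 1e-9) abort("`class_mix` must sum to 1.")
  if (!all(names(class_mix) %in% c("sdn", "ddn", "nshdn", "hdn"))) {
    abort("Unknown class in `class_mix` (use sdn/ddn/nshdn/hdn).")
  }
  if (any(c(size_cv, contrast_cv) < 0) || dose <= 0) {
    abort("CVs must be >= 0 and dose > 0.")
  }
  if (length(size_cv) == 1) size_cv <- rep(size_cv, 2)
  structure(list(n_images = n_images, class_mix = class_mix,
                 size_cv = size_cv, contrast_cv = contrast_cv, dose = dose,
                 seed = as.integer(seed), raster = raster,
                 probe_fwhm = probe_fwhm),
            class = "lv_population_spec")
}

#' Generate a synthetic image population with ground truth
#'
#' Per image: a structure class is drawn from the mix; lateral dimensions
#' from normals at the design values with the spec's CVs; orientation
#' uniform on [0, 180); placement uniform with a margin that prevents border
#' clipping; a unit-mean multiplicative contrast scale with SD
#' `contrast_cv`. The template is rendered analytically, contrast-scaled,
#' blurred, shot-noised and quantized. DF and SE channels are produced from
#' the same template. Every image is reproducible from its recorded seed.
#'
#' @param spec An [population_spec()].
#' @param beam,detector Imaging condition.
#' @param channels Channels to render (`"DF"` and/or `"SE"`).
#' @param ... Physics options passed to [render_expected_signal()].
#' @return A list with `images` (tibble: `id`, `class`, list-columns
#'   `df`/`se` of [stem_image()]s) and `truth` (tibble of generator ground
#'   truth per image).
#' @export
generate_population <- function(spec, beam = 30,
                                detector = annular_detector(15, 55),
                                channels = "DF", ...) {
  stopifnot(inherits(spec, "lv_population_spec"))
  classes <- names(spec$class_mix)
  r <- spec$raster
  fw <- (c(r$nx, r$ny) - 1) * r$pixel_size  # field width/height, nm
  rows <- lapply(seq_len(spec$n_images), function(i) {
    iseed <- derive_seed(spec$seed, i)
    set.seed(iseed)
    cls <- sample(classes, 1, prob = spec$class_mix)
    L <- rnorm(1, 59.2, spec$size_cv[1] * 59.2)
    W <- rnorm(1, 28.5, spec$size_cv[2] * 28.5)
    # truncate at ~3 sigma so every structure fits the field with margin
    L <- min(max(L, 20), 71); W <- min(max(W, 10), 38)
    if (W > L) { tmp <- L; L <- W; W <- tmp }
    k <- max(rnorm(1, 1, spec$contrast_cv), 0.2)
    ori <- runif(1, 0, 180)
    margin <- sqrt(L^2 + W^2) / 2 + 10 * r$pixel_size
    pos1 <- function(half) if (half > margin) runif(1, -half + margin,
                                                    half - margin) else 0
    cx <- pos1(fw[1] / 2)
    cy <- pos1(fw[2] / 2)
    tpl <- structure_template(cls, length = L, width = W,
                              position = c(cx, cy), orientation = ori)
    img <- render_template(tpl, spec, beam, detector, contrast_scale = k,
                           rng_seed = iseed, channels = channels, ...)
    tibble(
      id = i, class = cls, length = L, width = W,
      n_layers = tpl$n_layers, contrast_scale = k,
      orientation = ori, x = cx, y = cy,
      hole_length = if (cls %in% c("nshdn", "hdn")) tpl$hole_length else NA_real_,
      hole_width = if (cls %in% c("nshdn", "hdn")) tpl$hole_width else NA_real_,
      aunp_diameter = if (cls == "hdn") tpl$aunp_diameter else NA_real_,
      seed = iseed,
      df = if ("DF" %in% channels) list(img$df) else list(NULL),
      se = if ("SE" %in% channels) list(img$se) else list(NULL)
    )
  })
  truth <- bind_rows(rows)
  list(images = truth[, c("id", "class", "df", "se")],
       truth = select(truth, -"df", -"se"))
}

# render one template to DF (and SE) stem images
render_template <- function(template, spec, beam, detector, contrast_scale = 1,
                            rng_seed = 1, channels = "DF", ...) {
  r <- spec$raster
  maps <- project_mass_thickness(template, r)
  out <- list()
  if ("DF" %in% channels) {
    S <- render_expected_signal(maps, beam, detector, ...)
    bg <- S[1, 1]  # corner pixel is bare film by the placement margin
    S <- bg + contrast_scale * (S - bg)
    out$df <- degrade(S, r$pixel_size, spec$probe_fwhm, spec$dose,
                      rng_seed = rng_seed, channel = "DF",
                      provenance = list(class = template$class,
                                        contrast_scale = contrast_scale))
  }
  if ("SE" %in% channels) {
    yields <- c(dna = 0.05, carbon = 0.05, gold = 1)
    se_exp <- matrix(yields["carbon"], r$ny, r$nx)
    se_exp[maps$gold > 0] <- yields["gold"]
    out$se <- degrade(se_exp, r$pixel_size, spec$probe_fwhm, spec$dose,
                      rng_seed = rng_seed + 1L, channel = "SE",
                      provenance = list(class = template$class))
  }
  out
}
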