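#' Run configuration
#'
#' Validated configuration binding the pipeline together. Defaults
#' reproduce the imaging condition of the study: 30 keV, 15-55 mrad
#' annulus, 3 nm carbon support.
#'
#' @param config Named list (e.g. from [read_run_config()]) overriding the
#'   defaults; unknown fields are an error, reported with their path.
#' @return An `lv_run_config` (validated named list).
#' @export
run_config <- function(config = list()) {
  defaults <- list(
    beam = list(energy_kev = 30),
    detector = list(inner_mrad = 15, outer_mrad = 55),
    physics = list(channel = "both", model = "difference",
                   relativistic = FALSE, delta_e_ev = 20),
    support = list(material = "carbon", thickness = 3),
    materials_file = NULL,
    scene = list(preset = "sdn"),
    mc = list(electrons_per_pixel = 200, raster = list(nx = 64, ny = 48,
                                                       pixel_size = 1)),
    population = list(n_images = 10, class_mix = list(sdn = 1),
                      size_cv = c(4.1 / 61.5, 4.0 / 37.5),
                      contrast_cv = 0.15, dose = 200,
                      raster = list(nx = 224, ny = 176, pixel_size = 0.5),
                      probe_fwhm = 1.5),
    analysis = list(min_area = 200, k = 3, inset = 0.2, gap = 4,
                    reference = "all", layer_model = "thin"),
    layers = list(unit_thickness = 7.4, n_max = 4),
    output_dir = "lvstem-out",
    seed = 1,
    verbose = TRUE
  )
  cfg <- merge_config(defaults, config, path = "")
  check <- function(ok, path, msg) {
    if (!ok) abort(sprintf("Invalid config at `%s`: %s", path, msg))
  }
  check(is.numeric(cfg$beam$energy_kev) && cfg$beam$energy_kev > 0,
        "beam.energy_kev", "must be a positive energy in keV")
  check(is.numeric(cfg$detector$inner_mrad) && is.numeric(cfg$detector$outer_mrad) &&
          cfg$detector$inner_mrad >= 0 &&
          cfg$detector$outer_mrad > cfg$detector$inner_mrad,
        "detector", "needs 0 <= inner_mrad < outer_mrad")
  check(cfg$physics$channel %in% c("both", "elastic", "inelastic"),
        "physics.channel", "must be both/elastic/inelastic")
  check(cfg$physics$model %in% c("difference", "collection"),
        "physics.model", "must be difference/collection")
  check(cfg$mc$electrons_per_pixel >= 1, "mc.electrons_per_pixel", "must be >= 1")
  mix <- unlist(cfg$population$class_mix)
  check(abs(sum(mix) - 1) < 1e-9, "population.class_mix", "fractions must sum to 1")
  check(all(names(mix) %in% c("sdn", "ddn", "nshdn", "hdn")),
        "population.class_mix", "unknown class (use sdn/ddn/nshdn/hdn)")
  check(cfg$population$dose > 0, "population.dose", "must be > 0")
  check(is.numeric(cfg$seed), "seed", "must be an integer")
  structure(cfg, class = "lv_run_config")
}

merge_config <- function(defaults, user, path) {
  if (length(user) == 0) return(defaults)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    abort(sprintf("Unknown config field `%s`.",
                  paste0(sub("^\\.", "", paste0(path, ".", extra[1])))))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, ".", nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' @rdname run_config
#' @param file YAML config file path.
#' @export
read_run_config <- function(file) run_config(yaml::read_yaml(file))

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

cfg_detector <- function(cfg) annular_detector(cfg$detector$inner_mrad,
                                               cfg$detector$outer_mrad)
cfg_beam <- function(cfg) beam_condition(cfg$beam$energy_kev)
cfg_raster <- function(r) image_raster(r$nx, r$ny, r$pixel_size)

say <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))
}

write_result_csv <- function(df, cfg, path) {
  df$config_hash <- config_hash(cfg)
  df$seed <- cfg$seed
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline runners
#'
#' Thin entry points binding the modules together, suitable for scripted
#' use or the shipped command-line wrapper (`inst/cli/lvstem.R`):
#' * `run_predict()` writes the analytic contrast predictions, the
#'   layer-ratio table and the voltage-ratio table;
#' * `run_simulate()` writes a Monte Carlo DF image (16-bit TIFF of counts
#'   with YAML sidecar);
#' * `run_synth()` writes a synthetic population (8-bit PNGs) and its
#'   ground-truth CSV;
#' * `run_analyze()` reads micrographs and writes per-structure and summary
#'   CSVs.
#'
#' Every CSV embeds the config hash and master seed, so identical configs
#' reproduce identical tables.
#'
#' @param cfg An [run_config()].
#' @param images For `run_analyze()`: directory of images, vector of paths,
#'   or list of [stem_image()]s.
#' @return Paths of the written outputs (invisibly for the writers);
#'   `run_analyze()` returns the measurement tibble invisibly.
#' @name runners
NULL

#' @rdname runners
#' @export
run_predict <- function(cfg = run_config()) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  beam <- cfg_beam(cfg); det <- cfg_detector(cfg)
  say(cfg, "predict: %g keV, %g-%g mrad, channel=%s, model=%s, relativistic=%s",
      beam$energy_kev, det$inner_mrad, det$outer_mrad, cfg$physics$channel,
      cfg$physics$model, cfg$physics$relativistic)
  phys <- list(channel = cfg$physics$channel, model = cfg$physics$model,
               delta_e_ev = cfg$physics$delta_e_ev,
               relativistic = cfg$physics$relativistic)
  support <- layer_stack(layers = list(list(
    material = as_material(cfg$support$material),
    thickness = cfg$support$thickness)), label = "film")
  ut <- cfg$layers$unit_thickness
  stacks <- lapply(seq_len(cfg$layers$n_max), function(n) {
    layer_stack(layers = c(support$layers,
                           list(list(material = as_material("dna"),
                                     thickness = n * ut))),
                label = sprintf("film+%dx%.3gnm DNA", n, ut))
  })
  pred <- bind_rows(lapply(stacks, function(s)
    do.call(predict_contrast, c(list(s, support, beam, det), phys))))
  pred$n_layers <- seq_len(cfg$layers$n_max)
  pred$layer_ratio <- pred$contrast / pred$contrast[1]
  p1 <- write_result_csv(pred, cfg, file.path(cfg$output_dir, "predictions.csv"))
  vr <- tibble(
    energy_lo_kev = beam$energy_kev, energy_hi_kev = 300,
    ratio = do.call(voltage_signal_ratio,
                    c(list(stacks[[1]], beam, 300, det, det), phys)))
  p2 <- write_result_csv(vr, cfg, file.path(cfg$output_dir, "voltage_ratio.csv"))
  say(cfg, "predict: 2-layer/1-layer contrast ratio = %.4f, 30/300 keV signal ratio = %.3f",
      pred$layer_ratio[2], vr$ratio[1])
  invisible(c(p1, p2))
}

#' @rdname runners
#' @export
run_simulate <- function(cfg = run_config()) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  scene <- if (!is.null(cfg$scene$file)) {
    read_scene(cfg$scene$file)
  } else {
    presets <- c("sdn", "ddn", "nshdn", "hdn")
    if (!cfg$scene$preset %in% presets) {
      abort(sprintf("Unknown scene preset '%s'; available presets: %s.",
                    cfg$scene$preset, paste(presets, collapse = ", ")))
    }
    scene_preset(cfg$scene$preset)
  }
  say(cfg, "simulate: preset=%s, %d e-/px", cfg$scene$preset %||% "(file)",
      cfg$mc$electrons_per_pixel)
  mc <- mc_config(electrons_per_pixel = cfg$mc$electrons_per_pixel,
                  rng_seed = cfg$seed, channel =
                    if (cfg$physics$channel == "elastic") "elastic" else "both",
                  delta_e_ev = cfg$physics$delta_e_ev,
                  relativistic = cfg$physics$relativistic)
  img <- simulate_df_image(scene, cfg_beam(cfg), cfg_detector(cfg), mc,
                           cfg_raster(cfg$mc$raster))
  path <- file.path(cfg$output_dir, sprintf("mc_%s.tif",
                                            cfg$scene$preset %||% "scene"))
  write_stem_image(img, path, what = "counts")
  invisible(path)
}

#' @rdname runners
#' @export
run_synth <- function(cfg = run_config()) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$population
  spec <- population_spec(n_images = p$n_images,
                          class_mix = unlist(p$class_mix),
                          size_cv = unlist(p$size_cv),
                          contrast_cv = p$contrast_cv, dose = p$dose,
                          seed = cfg$seed, raster = cfg_raster(p$raster),
                          probe_fwhm = p$probe_fwhm)
  pop <- generate_population(spec, cfg_beam(cfg), cfg_detector(cfg),
                             channels = c("DF", "SE"),
                             channel = cfg$physics$channel,
                             model = cfg$physics$model,
                             delta_e_ev = cfg$physics$delta_e_ev,
                             relativistic = cfg$physics$relativistic)
  for (i in seq_len(nrow(pop$images))) {
    write_stem_image(pop$images$df[[i]],
                     file.path(cfg$output_dir, sprintf("img_%03d_df.png", i)))
    write_stem_image(pop$images$se[[i]],
                     file.path(cfg$output_dir, sprintf("img_%03d_se.png", i)))
  }
  truth_path <- file.path(cfg$output_dir, "ground_truth.csv")
  write_result_csv(pop$truth, cfg, truth_path)
  say(cfg, "synth: wrote %d image pairs + %s", nrow(pop$images), truth_path)
  invisible(truth_path)
}

#' @rdname runners
#' @param rois Optional manual ROI boxes for `run_analyze()`: a list of
#'   [roi_pair()]s per image (named by file name or positional). When given,
#'   segmentation is skipped and contrast is measured for exactly those
#'   boxes.
#' @export
run_analyze <- function(cfg = run_config(), images, rois = NULL) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(images) && length(images) == 1 && dir.exists(images)) {
    images <- list.files(images, pattern = "(?i)\\.(png|tif|tiff)$",
                         full.names = TRUE)
  }
  if (length(images) == 0) abort("No input images to analyze.")
  a <- cfg$analysis
  tabs <- list(); failed <- 0
  for (i in seq_along(images)) {
    img <- images[[i]]
    name <- if (is.character(img)) basename(img) else sprintf("image_%03d", i)
    img <- tryCatch(
      if (is.character(img)) read_stem_image(img) else img,
      error = function(e) { warn(sprintf("Skipping %s: %s", name,
                                         conditionMessage(e))); NULL })
    if (is.null(img)) { failed <- failed + 1; next }
    if (!is.null(rois)) {
      rp <- rois[[if (!is.null(names(rois)) && name %in% names(rois)) name else i]]
      tab <- roi_contrast(img, rp)
      tab$id <- 1L
    } else {
      tab <- analyze_image(img, min_area = a$min_area, k = a$k,
                           inset = a$inset, gap = a$gap)
    }
    if (nrow(tab)) { tab$image <- name; tabs[[length(tabs) + 1]] <- tab }
  }
  if (failed == length(images)) abort("All input images failed to read.")
  meas <- bind_rows(tabs)
  if (nrow(meas)) {
    meas <- normalize_ratios(meas, reference = a$reference)
    meas$layer_call <- classify_layers(meas$ratio, model = a$layer_model,
                                       n_max = cfg$layers$n_max)
  }
  write_result_csv(meas, cfg, file.path(cfg$output_dir, "measurements.csv"))
  if (nrow(meas)) {
    write_result_csv(population_stats(meas), cfg,
                     file.path(cfg$output_dir, "summary.csv"))
  }
  say(cfg, "analyze: %d structures in %d image(s)", nrow(meas),
      length(images) - failed)
  invisible(meas)
}
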