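#' Layered specimen stack
#'
#' An ordered list of (material, thickness) layers along the beam.
#'
#' @param ... Layers given as `material = thickness_nm` pairs, where the name
#'   is a library material name, or `lv_material` objects alternating with
#'   thicknesses.
#' @param label Stack label.
#' @param layers Optionally, a ready-made list of `list(material=, thickness=)`.
#' @return An `lv_layer_stack`.
#' @examples
#' layer_stack(carbon = 3, dna = 7.4, label = "film+sDN")
#' @export
layer_stack <- function(..., label = NULL, layers = NULL) {
  if (is.null(layers)) {
    args <- list(...)
    if (length(args) == 0) abort("A stack needs at least one layer.")
    nms <- names(args)
    layers <- map2(nms, args, function(nm, t) {
      list(material = as_material(nm), thickness = as.numeric(t))
    })
  }
  for (l in layers) {
    if (!is.numeric(l$thickness) || l$thickness <= 0) {
      abort("Layer thicknesses must be > 0.")
    }
  }
  structure(list(layers = layers,
                 label = label %||% paste(map_chr_(layers, function(l)
                   sprintf("%s %.3gnm", l$material$name, l$thickness)),
                   collapse = " + ")),
            class = "lv_layer_stack")
}

map_chr_ <- function(x, f) vapply(x, f, character(1))

#' @export
print.lv_layer_stack <- function(x, ...) {
  cat(sprintf("<lv_layer_stack> %s\n", x$label)); invisible(x)
}

# per-stack attenuation exponents; tables cached per call site
stack_tables <- function(stack, beam, detector, channel, delta_e_ev,
                         relativistic, theta_max_mrad) {
  mats <- unique(map_chr_(stack$layers, function(l) l$material$name))
  tabs <- lapply(stack$layers, function(l)
    build_scattering_table(l$material, beam, detector, channel = channel,
                           delta_e_ev = delta_e_ev, relativistic = relativistic,
                           theta_max_mrad = theta_max_mrad))
  tabs
}

#' Detected dark-field signal fraction of a layer stack
#'
#' Single-scattering annular DF model. With per-layer scattering power
#' \eqn{s(\theta) = \sum_i t_i / \Lambda_i(\theta)} (mean free path for
#' scattering beyond \eqn{\theta}), the default `"difference"` model detects
#' \eqn{S = e^{-s(\theta_{out})} - e^{-s(\theta_{in})}}: the fraction
#' scattered once into the annulus. The `"collection"` model is the classic
#' saturating mass-thickness law \eqn{S = 1 - e^{-\sum_i t_i/\Lambda_{det,i}}}
#' built on the annulus mean free path alone (no out-scattering loss).
#' Both reduce to \eqn{\sum_i t_i/\Lambda_{det,i}} in the thin limit.
#'
#' @param stack An [layer_stack()].
#' @param beam Beam condition or energy in keV.
#' @param detector An [annular_detector()].
#' @param channel,delta_e_ev,relativistic,theta_max_mrad Passed to
#'   [build_scattering_table()].
#' @param model `"difference"` (default) or `"collection"`.
#' @return Detected electron fraction in `[0, 1]`.
#' @examples
#' df_signal_fraction(layer_stack(carbon = 3, dna = 7.4), 30, annular_detector(15, 55))
#' @export
df_signal_fraction <- function(stack, beam, detector,
                               channel = c("both", "elastic", "inelastic"),
                               model = c("difference", "collection"),
                               delta_e_ev = 20, relativistic = FALSE,
                               theta_max_mrad = 500 * pi) {
  channel <- match.arg(channel)
  model <- match.arg(model)
  stopifnot(inherits(stack, "lv_layer_stack"))
  tabs <- stack_tables(stack, beam, detector, channel, delta_e_ev,
                       relativistic, theta_max_mrad)
  t_i <- vapply(stack$layers, function(l) l$thickness, numeric(1))
  if (model == "collection") {
    s_det <- sum(t_i * vapply(tabs, function(tb) 1 / tb$lambda_det, numeric(1)))
    return(1 - exp(-s_det))
  }
  s_in <- sum(t_i * vapply(tabs, mu_beyond, numeric(1),
                           theta_mrad = detector$inner_mrad))
  s_out <- sum(t_i * vapply(tabs, mu_beyond, numeric(1),
                            theta_mrad = detector$outer_mrad))
  exp(-s_out) - exp(-s_in)
}

#' Predicted ROI contrast of a structure stack against a background stack
#'
#' Contrast is `(I_D - I_B) / I_B` on the two model DF signals.
#'
#' @param structure_stack,background_stack [layer_stack()] objects.
#' @inheritParams df_signal_fraction
#' @return A one-row tibble: labels, the two signal fractions, and `contrast`.
#' @examples
#' predict_contrast(layer_stack(carbon = 3, dna = 7.4), layer_stack(carbon = 3),
#'                  30, annular_detector(15, 55))
#' @export
predict_contrast <- function(structure_stack, background_stack, beam, detector,
                             ...) {
  s_d <- df_signal_fraction(structure_stack, beam, detector, ...)
  s_b <- df_signal_fraction(background_stack, beam, detector, ...)
  if (s_b <= 0) abort("Background signal is zero; contrast undefined.")
  beam <- as_beam(beam)
  tibble(
    structure = structure_stack$label, background = background_stack$label,
    energy_kev = beam$energy_kev,
    inner_mrad = detector$inner_mrad, outer_mrad = detector$outer_mrad,
    signal_structure = s_d, signal_background = s_b,
    contrast = (s_d - s_b) / s_b
  )
}

#' Contrast ratio of an n-layer structure to a single layer
#'
#' Ratio of the predicted contrast of `n_layers` stacked unit layers to that
#' of one unit layer, both on the same support. Equals `n` in the thin limit
#' and falls below `n` as scattering saturates.
#'
#' @param n_layers Integer >= 1.
#' @param unit_thickness Thickness of one layer, nm.
#' @param layer_material Material of the layers (default `"dna"`).
#' @param support Support stack (default 3 nm carbon).
#' @inheritParams df_signal_fraction
#' @return Dimensionless ratio.
#' @examples
#' layer_contrast_ratio(2, 7.4, beam = 30, detector = annular_detector(15, 55))
#' @export
layer_contrast_ratio <- function(n_layers, unit_thickness = 7.4,
                                 layer_material = "dna",
                                 support = layer_stack(carbon = 3),
                                 beam = 30, detector = annular_detector(15, 55),
                                 ...) {
  if (n_layers < 1) abort("`n_layers` must be >= 1.")
  if (n_layers == 1) return(1)
  mat <- as_material(layer_material)
  stk <- function(n) layer_stack(layers = c(support$layers,
                                            list(list(material = mat,
                                                      thickness = n * unit_thickness))))
  s0 <- df_signal_fraction(support, beam, detector, ...)
  s1 <- df_signal_fraction(stk(1), beam, detector, ...)
  sn <- df_signal_fraction(stk(n_layers), beam, detector, ...)
  (sn - s0) / (s1 - s0)
}

#' Ratio of detected DF signals at two beam energies
#'
#' The low-voltage advantage: detected signal fraction of the same specimen
#' stack at `beam_lo` over that at `beam_hi`, each with its own detector.
#'
#' @param stack The specimen [layer_stack()].
#' @param beam_lo,beam_hi Beam conditions or energies in keV.
#' @param det_lo,det_hi Detectors for the two conditions (default: the same
#'   15-55 mrad annulus).
#' @inheritParams df_signal_fraction
#' @return Dimensionless signal ratio.
#' @examples
#' voltage_signal_ratio(layer_stack(carbon = 3, dna = 7.4), 30, 300)
#' @export
voltage_signal_ratio <- function(stack, beam_lo, beam_hi,
                                 det_lo = annular_detector(15, 55),
                                 det_hi = det_lo, ...) {
  s_lo <- df_signal_fraction(stack, beam_lo, det_lo, ...)
  s_hi <- df_signal_fraction(stack, beam_hi, det_hi, ...)
  if (s_hi <= 0) abort("High-voltage signal is zero; ratio undefined.")
  s_lo / s_hi
}

#' Contrast versus layer thickness
#'
#' @param material Layer material (object or library name).
#' @param support Support [layer_stack()].
#' @param beam,detector Beam and detector.
#' @param thickness_grid Positive thicknesses, nm.
#' @inheritParams df_signal_fraction
#' @return Tibble of `(thickness, signal, contrast)`, monotone increasing.
#' @export
contrast_vs_thickness_curve <- function(material, support = layer_stack(carbon = 3),
                                        beam = 30,
                                        detector = annular_detector(15, 55),
                                        thickness_grid, ...) {
  if (length(thickness_grid) == 0 || any(thickness_grid <= 0)) {
    abort("`thickness_grid` must be non-empty and positive.")
  }
  mat <- as_material(material)
  s0 <- df_signal_fraction(support, beam, detector, ...)
  out <- tibble(
    thickness = as.numeric(thickness_grid),
    signal = map_dbl(thickness_grid, function(t) {
      stk <- layer_stack(layers = c(support$layers,
                                    list(list(material = mat, thickness = t))))
      df_signal_fraction(stk, beam, detector, ...)
    })
  )
  out$contrast <- (out$signal - s0) / s0
  class(out) <- c("lv_contrast_curve", class(out))
  out
}

#' @export
autoplot.lv_contrast_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$thickness, y = .data$contrast)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "layer thickness (nm)", y = "predicted DF contrast")
}
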