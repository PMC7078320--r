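#' Fill contrast ratios against a reference set
#'
#' Divides each contrast by the mean contrast of the reference selection:
#' `"all"` (the whole table), `"class"` (per-class means), or an explicit
#' vector of row ids. After `"all"` normalization the mean ratio over the
#' table is exactly 1.
#'
#' @param measurements Tibble with a `contrast` column (and `class`/`id` as
#'   needed by the selector).
#' @param reference `"all"`, `"class"`, or integer ids matching an `id`
#'   column.
#' @return The tibble with the `ratio` column filled.
#' @export
normalize_ratios <- function(measurements, reference = "all") {
  m <- measurements
  if (nrow(m) == 0) abort("Empty measurement table.")
  if (identical(reference, "all")) {
    ref <- mean(m$contrast)
    if (ref == 0) abort("Zero reference mean contrast.")
    m$ratio <- m$contrast / ref
  } else if (identical(reference, "class")) {
    if (!"class" %in% names(m)) abort("Per-class normalization needs a `class` column.")
    m <- m |>
      group_by(.data$class) |>
      mutate(ratio = .data$contrast / mean(.data$contrast)) |>
      ungroup()
  } else {
    sel <- if ("id" %in% names(m)) m$id %in% reference else rep(FALSE, nrow(m))
    if (!any(sel)) abort("Reference selection is empty.")
    ref <- mean(m$contrast[sel])
    if (ref == 0) abort("Zero reference mean contrast.")
    m$ratio <- m$contrast / ref
  }
  m
}

#' Layer-number call from a contrast ratio
#'
#' `"thin"` model: the ratio itself estimates the layer count (nearest
#' integer). `"saturating"` model: nearest `n` minimizing
#' `|ratio - layer_contrast_ratio(n)|` under the package's DF model. Ties
#' break toward the smaller layer count.
#'
#' @param ratio Positive contrast ratio(s).
#' @param model `"thin"` or `"saturating"`.
#' @param n_max Largest layer count considered.
#' @param predictions Optional precomputed ratio predictions for `1:n_max`
#'   (recomputed from [layer_contrast_ratio()] if missing).
#' @param ... Passed to [layer_contrast_ratio()].
#' @return Integer layer calls.
#' @examples
#' classify_layers(c(1.02, 1.94))
#' @export
classify_layers <- function(ratio, model = c("thin", "saturating"),
                            n_max = 4, predictions = NULL, ...) {
  model <- match.arg(model)
  if (any(ratio <= 0)) abort("`ratio` must be > 0.")
  preds <- if (model == "thin") seq_len(n_max)
  else predictions %||% vapply(seq_len(n_max), layer_contrast_ratio,
                               numeric(1), ...)
  vapply(ratio, function(r) {
    d <- abs(r - preds)
    which(d <= min(d) + 1e-12)[1]  # ties toward smaller n
  }, integer(1))
}

#' Intensity line profile
#'
#' Bilinear interpolation along the segment from `start` to `end` (pixel
#' coordinates, `c(row, col)`, 1-based), averaged over `width_px` parallel
#' lines perpendicular to the segment.
#'
#' @param image An [stem_image()].
#' @param start,end Endpoints `c(row, col)`.
#' @param width_px Averaging width, pixels.
#' @param n Number of samples (default: one per pixel of length).
#' @return Tibble (class `lv_profile`) of `position_nm`, `intensity`.
#' @export
line_profile <- function(image, start, end, width_px = 1, n = NULL) {
  px <- image_values(image)
  v <- c(end[1] - start[1], end[2] - start[2])
  len <- sqrt(sum(v^2))
  if (len == 0) abort("Zero-length profile line.")
  u <- v / len
  perp <- c(-u[2], u[1])
  n <- n %||% (ceiling(len) + 1)
  tpos <- seq(0, len, length.out = n)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = max(width_px, 1))
  vals <- vapply(tpos, function(t) {
    p <- c(start[1] + t * u[1], start[2] + t * u[2])
    mean(vapply(offs, function(o)
      bilinear(px, p[1] + o * perp[1], p[2] + o * perp[2]), numeric(1)))
  }, numeric(1))
  out <- tibble(position_nm = tpos * image$pixel_size, intensity = vals)
  class(out) <- c("lv_profile", class(out))
  out
}

bilinear <- function(px, r, c) {
  r <- min(max(r, 1), nrow(px)); c <- min(max(c, 1), ncol(px))
  r0 <- floor(r); c0 <- floor(c)
  r1 <- min(r0 + 1, nrow(px)); c1 <- min(c0 + 1, ncol(px))
  fr <- r - r0; fc <- c - c0
  (1 - fr) * ((1 - fc) * px[r0, c0] + fc * px[r0, c1]) +
    fr * ((1 - fc) * px[r1, c0] + fc * px[r1, c1])
}

#' @export
autoplot.lv_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position_nm,
                                       y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (nm)", y = "intensity")
}

#' Detect a through-hole inside a structure footprint
#'
#' Looks for interior pixels statistically consistent with the background
#' level: pixels inside the footprint's filled hull but below the
#' segmentation threshold form candidate components; the largest one is
#' kept if its area is at least `min_frac` of the hull area and its mean
#' intensity is consistent with the background level (within
#' `qnorm(1 - alpha/2) + 1` background SDs, the +1 allowing for rim blur).
#'
#' @param segmentation An [segment_structures()] result.
#' @param id Footprint id.
#' @param min_frac Minimum hole area as a fraction of the hull area.
#' @param alpha Significance level of the background-consistency test.
#' @return One-row tibble: `hole_detected`, `hole_length`, `hole_width`
#'   (nm, min-area rectangle), `hole_area_nm2`.
#' @export
detect_hole <- function(segmentation, id, min_frac = 0.05, alpha = 0.01) {
  seg <- segmentation
  img <- attr(seg, "image")
  px <- image_values(img)
  labels <- attr(seg, "labels")
  mask <- labels == id
  filled <- EBImage::fillHull(mask + 0) > 0
  interior <- filled & !mask
  none <- tibble(hole_detected = FALSE, hole_length = NA_real_,
                 hole_width = NA_real_, hole_area_nm2 = NA_real_)
  if (!any(interior)) return(none)
  cand <- EBImage::bwlabel(interior + 0)
  sizes <- tabulate(cand[cand > 0])
  lab <- which.max(sizes)
  idx <- which(cand == lab, arr.ind = TRUE)
  hull_area <- sum(filled)
  if (nrow(idx) < min_frac * hull_area) return(none)
  bg <- attr(seg, "background_level"); bsd <- attr(seg, "background_sd")
  # interior pixels sit under the blurred rim, so their mean runs slightly
  # above bare background; accept if within `z_max` background SDs of it
  z_max <- qnorm(1 - alpha / 2) + 1
  if (mean(px[cand == lab]) >= bg + z_max * bsd) return(none)
  # refine the hole boundary to the 50% edge criterion on a lightly
  # smoothed image (the raw threshold sits low on the rim transition)
  sm <- blur_map(px, 2.355)
  plateau <- median(px[mask])
  ref <- (filled & sm < (bg + plateau) / 2) + 0
  comp <- EBImage::bwlabel(ref)
  ctr <- round(colMeans(idx))
  lab2 <- comp[ctr[1], ctr[2]]
  if (lab2 > 0) idx <- which(comp == lab2, arr.ind = TRUE)
  if (nrow(idx) < 3) return(none)
  dims <- measure_dimensions(idx, img$pixel_size)
  tibble(hole_detected = TRUE, hole_length = dims$length,
         hole_width = dims$width,
         hole_area_nm2 = nrow(idx) * img$pixel_size^2)
}

#' Detect a bright nanoparticle inside a structure footprint
#'
#' Bright-blob detection: pixels inside the footprint's filled hull above
#' the structure's plateau level (median) plus `m` robust SDs form
#' candidate blobs; the largest is fit by its minimum enclosing circle.
#'
#' @param segmentation An [segment_structures()] result.
#' @param id Footprint id.
#' @param m Threshold in plateau robust SDs.
#' @param min_px Minimum blob size in pixels.
#' @return One-row tibble: `particle_detected`, `particle_diameter` (nm),
#'   `particle_row`, `particle_col`.
#' @export
detect_particle <- function(segmentation, id, m = 3, min_px = 8) {
  seg <- segmentation
  img <- attr(seg, "image")
  px <- image_values(img)
  labels <- attr(seg, "labels")
  mask <- EBImage::fillHull((labels == id) + 0) > 0
  # smoothing keeps shot noise from fragmenting the blob
  sm <- blur_map(px, 2.355)
  vals <- sm[mask]
  plateau <- median(vals)
  s <- max(mad(vals), 1e-9)
  blob <- mask & sm > plateau + m * s
  none <- tibble(particle_detected = FALSE, particle_diameter = NA_real_,
                 particle_row = NA_real_, particle_col = NA_real_)
  if (sum(blob) < min_px) return(none)
  # a real particle is bright on the contrast scale, not merely above the
  # plateau noise: require a level a fair fraction of the DNA-film step
  bg <- attr(seg, "background_level")
  level <- median(sm[blob])
  if (level - plateau < 0.5 * max(plateau - bg, 0)) return(none)
  # refine the blob edge to 50% between the plateau and the blob level
  blob <- mask & sm > (plateau + level) / 2
  if (sum(blob) < min_px) return(none)
  cand <- EBImage::bwlabel(blob + 0)
  sizes <- tabulate(cand[cand > 0])
  lab <- which.max(sizes)
  if (sizes[lab] < min_px) return(none)
  idx <- which(cand == lab, arr.ind = TRUE)
  circ <- enclosing_circle(idx)
  # area-equivalent diameter: robust against single noise-displaced
  # boundary pixels that inflate the enclosing circle
  tibble(particle_detected = TRUE,
         particle_diameter = (2 * sqrt(nrow(idx) / pi) + 1) * img$pixel_size,
         particle_row = circ$c[1], particle_col = circ$c[2])
}

# minimum enclosing circle (simple two-pass approximation: center from the
# two farthest hull points, then grow to cover all)
enclosing_circle <- function(idx) {
  pts <- cbind(idx[, 1], idx[, 2])
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  d2max <- 0; pair <- c(1, 1)
  nh <- nrow(hull)
  for (i in seq_len(nh)) for (j in seq_len(nh)) {
    d2 <- sum((hull[i, ] - hull[j, ])^2)
    if (d2 > d2max) { d2max <- d2; pair <- c(i, j) }
  }
  c0 <- (hull[pair[1], ] + hull[pair[2], ]) / 2
  r <- sqrt(max(rowSums(sweep(pts, 2, c0)^2)))
  list(c = c0, r = r)
}

#' Population summary statistics
#'
#' Per structure class: mean, SD (population convention: SD of a single
#' measurement is 0) and count of length, width, contrast and ratio.
#'
#' @param measurements Per-structure tibble with `class`, `length`, `width`,
#'   `contrast`, `ratio` columns.
#' @return Tidy tibble of `(class, metric, mean, sd, n)`.
#' @export
population_stats <- function(measurements) {
  if (nrow(measurements) == 0) abort("Empty measurement table.")
  m <- measurements
  if (!"class" %in% names(m)) m$class <- "all"
  long <- tidyr::pivot_longer(
    m[, c("class", intersect(c("length", "width", "contrast", "ratio"),
                             names(m)))],
    -"class", names_to = "metric", values_to = "value")
  long |>
    filter(!is.na(.data$value)) |>
    group_by(.data$class, .data$metric) |>
    summarise(mean = mean(.data$value),
              sd = if (n() > 1) sd(.data$value) else 0,
              n = n(), .groups = "drop")
}

#' Measure every structure in an image
#'
#' The full per-image pipeline: segmentation, rectangle morphometry,
#' automatic ROI contrast, and hole/particle detection, one row per
#' surviving footprint. Deterministic.
#'
#' @param image An [stem_image()] (DF channel drives segmentation).
#' @param min_area,k Segmentation parameters.
#' @param inset,gap ROI construction parameters.
#' @param detect Run hole/particle detectors (default TRUE).
#' @return Tibble with centroid, dimensions (nm), orientation, `I_D`,
#'   `I_B`, `contrast`, `ratio` (NA until normalized), hole and particle
#'   fields.
#' @export
analyze_image <- function(image, min_area = 200, k = 3, inset = 0.2, gap = 4,
                          detect = TRUE) {
  seg <- segment_structures(image, min_area = min_area, k = k)
  if (nrow(seg) == 0) {
    return(tibble(id = integer(), length = numeric(), width = numeric(),
                  orientation = numeric(), area_nm2 = numeric(),
                  I_D = numeric(), I_B = numeric(), contrast = numeric(),
                  ratio = numeric(), hole_detected = logical(),
                  particle_detected = logical()))
  }
  rows <- lapply(seg$id, function(i) {
    fp <- refine_footprint(seg, i)
    dims <- measure_dimensions(fp, image$pixel_size)
    cm <- roi_contrast(image, auto_roi(seg, i, inset = inset, gap = gap))
    out <- tibble(id = i, length = dims$length, width = dims$width,
                  orientation = dims$orientation,
                  area_nm2 = seg$area_nm2[match(i, seg$id)],
                  centroid_row = seg$centroid_row[match(i, seg$id)],
                  centroid_col = seg$centroid_col[match(i, seg$id)])
    out <- dplyr::bind_cols(out, cm)
    if (detect) {
      out <- dplyr::bind_cols(out, detect_hole(seg, i), detect_particle(seg, i))
    }
    out
  })
  out <- bind_rows(rows)
  # abutting structures merge into one component; flag area outliers
  out$merged_suspect <- nrow(out) >= 3 &
    out$area_nm2 > 1.8 * median(out$area_nm2)
  out
}
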