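#' Minimum-area enclosing rectangle of a pixel footprint
#'
#' Rotating-calipers over the convex hull of the pixel centers; reported
#' side lengths are padded by one pixel (half a pixel of support on each
#' side of the center grid). The long side is `length`.
#'
#' @param footprint Two-column matrix of (row, col) pixel coordinates.
#' @param pixel_size nm per pixel.
#' @return A list with `length`, `width` (nm), `orientation` (degrees in
#'   `[0, 180)`, direction of the long side), `center` (row, col).
#' @export
measure_dimensions <- function(footprint, pixel_size = 1) {
  if (is.null(dim(footprint)) || nrow(footprint) < 3) {
    abort("Footprint must contain at least 3 pixels.")
  }
  # x = col, y = -row: right-handed frame with angles as on-screen
  pts <- cbind(footprint[, 2], -footprint[, 1])
  hull <- unique(pts[grDevices::chull(pts), , drop = FALSE])
  if (nrow(hull) < 3 || qr(sweep(hull, 2, colMeans(hull)))$rank < 2) {
    abort("Degenerate (collinear) footprint.")
  }
  nh <- nrow(hull)
  edges <- hull[c(2:nh, 1), ] - hull
  ang <- atan2(edges[, 2], edges[, 1])
  best <- NULL
  for (a in unique(round(ang %% pi, 10))) {
    # rotate the hull by -a so the candidate edge direction lies along x
    rot <- cbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
    pr <- hull %*% rot
    d <- apply(pr, 2, function(u) diff(range(u)))
    area <- prod(d)
    if (is.null(best) || area < best$area) {
      best <- list(area = area, d = d, a = a)
    }
  }
  # extents re-measured in the optimal frame as the median of per-slice
  # extents: the enclosing-rectangle max statistic is otherwise inflated by
  # noise-displaced boundary pixels
  rot <- cbind(c(cos(best$a), sin(best$a)), c(-sin(best$a), cos(best$a)))
  pr_all <- pts %*% rot
  best$d <- pmin(best$d, c(sliced_extent(pr_all[, 2], pr_all[, 1]),
                           sliced_extent(pr_all[, 1], pr_all[, 2])))
  dims <- sort(best$d, decreasing = TRUE) + 1  # one-pixel support padding
  # orientation of the long side in image coordinates
  long_is_first <- best$d[1] >= best$d[2]
  ori <- if (long_is_first) best$a else best$a + pi / 2
  ori <- (ori * 180 / pi) %% 180
  list(length = dims[1] * pixel_size, width = dims[2] * pixel_size,
       orientation = ori,
       center = c(mean(range(footprint[, 1])), mean(range(footprint[, 2]))))
}

# median extent of `u` over slices of the perpendicular coordinate `v`
# (end slices excluded: they sample the rectangle corners)
sliced_extent <- function(v, u, slice_px = 4) {
  rng <- range(v)
  nb <- max(1, floor(diff(rng) / slice_px))
  if (nb < 3) return(diff(range(u)))
  b <- cut(v, seq(rng[1], rng[2], length.out = nb + 1), include.lowest = TRUE)
  ext <- tapply(u, b, function(x) diff(range(x)))
  ext <- ext[!is.na(ext)]
  if (length(ext) > 4) ext <- ext[2:(length(ext) - 1)]
  median(ext)
}

#' Automatic ROI box pair for a footprint
#'
#' The structure box is an axis-aligned box centered at the footprint's
#' interior-most pixel (distance-transform maximum), shrunk until it lies
#' entirely inside the footprint; the background box is an equally sized box
#' placed on adjacent bare support (first clear position among candidate
#' offsets around the structure), excluding every segmented footprint plus a
#' guard margin.
#'
#' @param segmentation An [segment_structures()] result.
#' @param id Footprint id to build ROIs for.
#' @param inset Fractional inset of the structure box relative to the
#'   footprint bounding box (default 0.2 per side).
#' @param gap Guard margin between footprints and the background box, px.
#' @return An `lv_roi_pair`: list of two boxes, each `c(row0, row1, col0,
#'   col1)` in 0-based half-open pixel coordinates.
#' @export
auto_roi <- function(segmentation, id, inset = 0.2, gap = 4) {
  seg <- segmentation
  fp <- seg$footprint[[match(id, seg$id)]]
  if (is.null(fp)) abort("Unknown footprint id.")
  labels <- attr(seg, "labels")
  nr <- nrow(labels); nc <- ncol(labels)
  # interior noise pores would cripple the distance transform: place the
  # structure box inside the morphologically closed footprint (closing seals
  # noise pores but preserves real openings like the nano-square hole)
  brush5 <- EBImage::makeBrush(5, "box")
  mask <- EBImage::erode(EBImage::dilate((labels == id) + 0, brush5), brush5) > 0
  dm <- EBImage::distmap(mask + 0)
  ctr <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  rr <- range(fp[, 1]); cr <- range(fp[, 2])
  half_r <- max(1, floor((1 - 2 * inset) * (diff(rr) + 1) / 2))
  half_c <- max(1, floor((1 - 2 * inset) * (diff(cr) + 1) / 2))
  lim <- max(1, floor(max(dm) - 1))
  half_r <- min(half_r, lim); half_c <- min(half_c, lim)
  box_ok <- function(b) {
    b[1] >= 1 && b[3] >= 1 && b[2] <= nr && b[4] <= nc &&
      all(mask[b[1]:b[2], b[3]:b[4]])
  }
  repeat {
    b <- c(ctr[1] - half_r, ctr[1] + half_r, ctr[2] - half_c, ctr[2] + half_c)
    if (box_ok(b)) break
    half_r <- half_r - 1; half_c <- max(1, half_c - 1)
    if (half_r < 1) abort("Footprint too small for a structure box.")
  }
  sbox <- b
  # background: clearest bare-support spot nearest the structure; every
  # segmented pixel (all ids) plus a guard margin is excluded
  occupied <- EBImage::dilate((labels > 0) + 0,
                              EBImage::makeBrush(2 * gap + 1, "box"))
  free <- (occupied == 0) + 0
  free[1, ] <- 0; free[nr, ] <- 0; free[, 1] <- 0; free[, nc] <- 0
  dmf <- EBImage::distmap(free)
  # shrink the background box to the largest clear pocket if space is tight
  bh <- min(half_r, half_c, floor(max(dmf) / sqrt(2)) - 1)
  if (bh < 3) abort("No clear background region found for ROI.")
  ok <- which(dmf >= (bh + 1) * sqrt(2), arr.ind = TRUE)
  if (nrow(ok) == 0) abort("No clear background region found for ROI.")
  ctr0 <- c(mean(rr), mean(cr))
  near <- which.min((ok[, 1] - ctr0[1])^2 + (ok[, 2] - ctr0[2])^2)
  c2 <- ok[near, ]
  bbox <- c(c2[1] - bh, c2[1] + bh, c2[2] - bh, c2[2] + bh)
  if (any(occupied[bbox[1]:bbox[2], bbox[3]:bbox[4]] > 0)) {
    abort("No clear background region found for ROI.")
  }
  structure(list(structure_box = c(sbox[1] - 1, sbox[2], sbox[3] - 1, sbox[4]),
                 background_box = c(bbox[1] - 1, bbox[2], bbox[3] - 1, bbox[4])),
            class = "lv_roi_pair")
}

#' Manual ROI box pair
#'
#' @param structure_box,background_box Boxes `c(row0, row1, col0, col1)` in
#'   0-based half-open pixel coordinates (row-major, origin top-left).
#' @return An `lv_roi_pair`.
#' @export
roi_pair <- function(structure_box, background_box) {
  for (b in list(structure_box, background_box)) {
    if (length(b) != 4 || b[2] <= b[1] || b[4] <= b[3]) {
      abort("Boxes must be c(row0, row1, col0, col1) with row1 > row0, col1 > col0.")
    }
  }
  if (boxes_overlap(structure_box, background_box)) {
    abort("ROI boxes must be disjoint.")
  }
  structure(list(structure_box = structure_box,
                 background_box = background_box), class = "lv_roi_pair")
}

boxes_overlap <- function(a, b) {
  a[1] < b[2] && b[1] < a[2] && a[3] < b[4] && b[3] < a[4]
}

box_mean <- function(px, b) {
  mean(px[(b[1] + 1):b[2], (b[3] + 1):b[4]])
}

#' ROI contrast measurement
#'
#' The study's contrast definition: `contrast = (I_D - I_B) / I_B` with
#' `I_D`, `I_B` the mean intensities over the structure and background
#' boxes. Intensities are the 8-bit display values when present (as an
#' image-tool measurement would use), else raw counts.
#'
#' @param image An [stem_image()].
#' @param rois An `lv_roi_pair` (from [auto_roi()] or [roi_pair()]).
#' @param offset Detector offset subtracted from both means before the
#'   ratio (default 0).
#' @return One-row tibble: `I_D`, `I_B`, `contrast` (`ratio` is filled
#'   later by [normalize_ratios()]).
#' @export
roi_contrast <- function(image, rois, offset = 0) {
  stopifnot(inherits(image, "lv_stem_image"), inherits(rois, "lv_roi_pair"))
  if (boxes_overlap(rois$structure_box, rois$background_box)) {
    abort("ROI boxes must be disjoint.")
  }
  px <- image_values(image)
  d <- dim(px)
  for (b in list(rois$structure_box, rois$background_box)) {
    if (b[1] < 0 || b[3] < 0 || b[2] > d[1] || b[4] > d[2]) {
      abort("ROI box outside the image.")
    }
  }
  I_D <- box_mean(px, rois$structure_box) - offset
  I_B <- box_mean(px, rois$background_box) - offset
  if (I_B <= 0) abort("Background intensity is zero; contrast undefined.")
  tibble(I_D = I_D, I_B = I_B, contrast = (I_D - I_B) / I_B,
         ratio = NA_real_)
}
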