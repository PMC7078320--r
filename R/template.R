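#' Structure template
#'
#' Parameterizes one DNA origami structure for the synthetic-image forward
#' model. Defaults are the design values: 59.2 x 28.5 nm slab, 7.4 nm per
#' layer, 15.6 x 14.2 nm hole (`nshdn`), 16 nm gold sphere (`hdn`).
#'
#' @param class `"sdn"`, `"ddn"`, `"nshdn"` or `"hdn"`.
#' @param length,width Lateral dimensions, nm.
#' @param thickness_per_layer Slab thickness per layer, nm.
#' @param n_layers Number of stacked layers (default 2 for `ddn`, else 1).
#' @param hole_length,hole_width Through-hole dimensions, nm.
#' @param aunp_diameter Gold sphere diameter, nm.
#' @param position Lateral center `c(x, y)`, nm.
#' @param orientation In-plane rotation, degrees.
#' @return An `lv_template`.
#' @examples
#' structure_template("nshdn")
#' @export
structure_template <- function(class = c("sdn", "ddn", "nshdn", "hdn"),
                               length = 59.2, width = 28.5,
                               thickness_per_layer = 7.4,
                               n_layers = NULL,
                               hole_length = 15.6, hole_width = 14.2,
                               aunp_diameter = 16,
                               position = c(0, 0), orientation = 0) {
  class <- match.arg(class)
  n_layers <- n_layers %||% if (class == "ddn") 2L else 1L
  if (length <= 0 || width <= 0 || thickness_per_layer <= 0 || n_layers < 1) {
    abort("Template dimensions must be positive and n_layers >= 1.")
  }
  if (class %in% c("nshdn", "hdn") &&
      (hole_length >= length || hole_width >= width)) {
    abort("Hole must fit inside the slab.")
  }
  structure(list(class = class, length = length, width = width,
                 thickness_per_layer = thickness_per_layer,
                 n_layers = as.integer(n_layers),
                 hole_length = hole_length, hole_width = hole_width,
                 aunp_diameter = aunp_diameter,
                 position = position, orientation = orientation),
            class = "lv_template")
}

#' @export
print.lv_template <- function(x, ...) {
  cat(sprintf("<lv_template> %s %.3g x %.3g nm, %d layer(s) x %.3g nm\n",
              x$class, x$length, x$width, x$n_layers, x$thickness_per_layer))
  invisible(x)
}

#' Convert a template to a 3D specimen scene
#'
#' The shared geometry between the fast analytic renderer and the Monte
#' Carlo simulator: the template's slab (holed for `nshdn`/`hdn`) sits on the
#' support; for `hdn` the gold sphere rests on the support, centered on the
#' hole.
#'
#' @param template An [structure_template()].
#' @param bounds Lateral window, nm.
#' @param support_material,support_thickness Support film.
#' @param dna_material Material of the origami slab.
#' @param aunp_material Material of the nanoparticle.
#' @return An `lv_scene`.
#' @export
template_to_scene <- function(template, bounds = c(-40, 40, -30, 30),
                              support_material = "carbon",
                              support_thickness = 3,
                              dna_material = "dna", aunp_material = "gold") {
  t <- template
  z0 <- support_thickness
  z1 <- z0 + t$n_layers * t$thickness_per_layer
  slab <- if (t$class %in% c("nshdn", "hdn")) {
    prim_holed_slab(t$position, t$length, t$width, t$orientation, z0, z1,
                    t$hole_length, t$hole_width, dna_material)
  } else {
    prim_slab(t$position, t$length, t$width, t$orientation, z0, z1,
              dna_material)
  }
  prims <- list(slab)
  if (t$class == "hdn") {
    r <- t$aunp_diameter / 2
    prims <- c(prims, list(prim_sphere(c(t$position, z0 + r),
                                       t$aunp_diameter, aunp_material)))
  }
  specimen_scene(prims, bounds = bounds,
                 support_material = support_material,
                 support_thickness = support_thickness)
}

#' Image raster geometry
#'
#' @param nx,ny Pixels along x (columns) and y (rows).
#' @param pixel_size nm per pixel.
#' @param origin Physical position `c(x, y)` of the center of pixel (1,1)
#'   (top-left), nm. Rows advance towards negative y so the raster is
#'   row-major with origin top-left.
#' @return An `lv_raster`.
#' @export
image_raster <- function(nx = 160, ny = 120, pixel_size = 0.5,
                         origin = NULL) {
  stopifnot(nx >= 1, ny >= 1, pixel_size > 0)
  origin <- origin %||% c(-(nx - 1) / 2 * pixel_size, (ny - 1) / 2 * pixel_size)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size = pixel_size, origin = origin),
            class = "lv_raster")
}

# physical coordinates of every pixel center, row-major
raster_coords <- function(raster) {
  x <- raster$origin[1] + (seq_len(raster$nx) - 1) * raster$pixel_size
  y <- raster$origin[2] - (seq_len(raster$ny) - 1) * raster$pixel_size
  list(x = matrix(rep(x, each = raster$ny), raster$ny, raster$nx),
       y = matrix(rep(y, times = raster$nx), raster$ny, raster$nx))
}

#' Project a template to per-material mass-thickness maps
#'
#' Per pixel: the DNA thickness (`n_layers * thickness_per_layer` inside the
#' footprint, 0 in the hole), the gold thickness (chord length through the
#' sphere) and the constant support thickness.
#'
#' @param template An [structure_template()].
#' @param raster An [image_raster()].
#' @param support_thickness Support film thickness, nm.
#' @return List of matrices `dna`, `gold`, `support` (ny x nx, nm).
#' @examples
#' maps <- project_mass_thickness(structure_template("sdn"), image_raster(80, 60, 1))
#' @export
project_mass_thickness <- function(template, raster, support_thickness = 3) {
  t <- template
  co <- raster_coords(raster)
  ar <- t$orientation * pi / 180
  hx <- (abs(t$length * cos(ar)) + abs(t$width * sin(ar))) / 2
  hy <- (abs(t$length * sin(ar)) + abs(t$width * cos(ar))) / 2
  xr <- range(co$x); yr <- range(co$y)
  if (t$position[1] - hx < xr[1] - raster$pixel_size ||
      t$position[1] + hx > xr[2] + raster$pixel_size ||
      t$position[2] - hy < yr[1] - raster$pixel_size ||
      t$position[2] + hy > yr[2] + raster$pixel_size) {
    abort("Template does not fit inside the raster window.")
  }
  a <- -t$orientation * pi / 180
  dx <- co$x - t$position[1]; dy <- co$y - t$position[2]
  u <- dx * cos(a) - dy * sin(a); v <- dx * sin(a) + dy * cos(a)
  inside <- abs(u) <= t$length / 2 & abs(v) <= t$width / 2
  if (t$class %in% c("nshdn", "hdn")) {
    inside <- inside & !(abs(u) < t$hole_length / 2 & abs(v) < t$hole_width / 2)
  }
  dna <- ifelse(inside, t$n_layers * t$thickness_per_layer, 0)
  gold <- matrix(0, raster$ny, raster$nx)
  if (t$class == "hdn") {
    r <- t$aunp_diameter / 2
    d2 <- dx^2 + dy^2
    gold <- ifelse(d2 <= r^2, 2 * sqrt(pmax(r^2 - d2, 0)), 0)
  }
  list(dna = dna, gold = gold,
       support = matrix(support_thickness, raster$ny, raster$nx))
}
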