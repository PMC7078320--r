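#' Specimen scene primitives
#'
#' A scene is an ordered list of 3D primitives over an infinite support slab;
#' at overlapping points the later (higher-priority) primitive wins.
#' Coordinates in nm: x, y lateral, z upward with the support slab occupying
#' `[0, support_thickness]`.
#'
#' `prim_slab()` is a rectangular slab with in-plane rotation,
#' `prim_holed_slab()` subtracts a concentric rectangular through-opening and
#' `prim_sphere()` a sphere.
#'
#' @param center Lateral center `c(x, y)` in nm (`prim_sphere()` takes
#'   `c(x, y, z)`).
#' @param length,width In-plane dimensions, nm (length >= width by convention).
#' @param orientation_deg In-plane rotation of the length axis, degrees.
#' @param z0,z1 Vertical extent, nm.
#' @param material Material object or library name.
#' @param hole_length,hole_width Through-opening dimensions, nm.
#' @param diameter Sphere diameter, nm.
#' @return A primitive object (`lv_primitive`).
#' @name scene-primitives
NULL

#' @rdname scene-primitives
#' @export
prim_slab <- function(center, length, width, orientation_deg = 0, z0, z1,
                      material) {
  stopifnot(length > 0, width > 0, z1 > z0)
  structure(list(type = "slab", center = center, length = length,
                 width = width, orientation = orientation_deg,
                 z0 = z0, z1 = z1, material = as_material(material)),
            class = "lv_primitive")
}

#' @rdname scene-primitives
#' @export
prim_holed_slab <- function(center, length, width, orientation_deg = 0,
                            z0, z1, hole_length, hole_width, material) {
  stopifnot(hole_length < length, hole_width < width,
            hole_length > 0, hole_width > 0)
  p <- prim_slab(center, length, width, orientation_deg, z0, z1, material)
  p$type <- "holed_slab"
  p$hole_length <- hole_length
  p$hole_width <- hole_width
  p
}

#' @rdname scene-primitives
#' @export
prim_sphere <- function(center, diameter, material) {
  stopifnot(length(center) == 3, diameter > 0)
  structure(list(type = "sphere", center = center, diameter = diameter,
                 material = as_material(material)),
            class = "lv_primitive")
}

#' Specimen scene
#'
#' @param primitives List of primitives, lowest priority first.
#' @param bounds Lateral simulation window `c(x0, x1, y0, y1)`, nm.
#' @param support_material,support_thickness The support film (default
#'   3 nm amorphous carbon at `z` in `[0, 3]`).
#' @return An `lv_scene`.
#' @export
specimen_scene <- function(primitives = list(), bounds = c(-40, 40, -30, 30),
                           support_material = "carbon", support_thickness = 3) {
  stopifnot(length(bounds) == 4, bounds[2] > bounds[1], bounds[4] > bounds[3])
  structure(list(primitives = primitives, bounds = bounds,
                 support = as_material(support_material),
                 support_thickness = support_thickness),
            class = "lv_scene")
}

#' @export
print.lv_scene <- function(x, ...) {
  cat(sprintf("<lv_scene> %d primitive(s) on %g nm %s, window [%g,%g]x[%g,%g] nm\n",
              length(x$primitives), x$support_thickness, x$support$name,
              x$bounds[1], x$bounds[2], x$bounds[3], x$bounds[4]))
  invisible(x)
}

# rotate lateral offsets into a primitive's frame
.to_frame <- function(px, py, prim) {
  a <- -prim$orientation * pi / 180
  dx <- px - prim$center[1]; dy <- py - prim$center[2]
  list(u = dx * cos(a) - dy * sin(a), v = dx * sin(a) + dy * cos(a))
}

# vectorized containment, boundary points belong to the primitive (half-open
# handling is done by priority: ties go to the higher-priority primitive)
prim_contains <- function(prim, x, y, z) {
  if (prim$type %in% c("slab", "holed_slab")) {
    fr <- .to_frame(x, y, prim)
    inside <- z >= prim$z0 & z < prim$z1 &
      abs(fr$u) <= prim$length / 2 & abs(fr$v) <= prim$width / 2
    if (prim$type == "holed_slab") {
      inside <- inside & !(abs(fr$u) < prim$hole_length / 2 &
                             abs(fr$v) < prim$hole_width / 2)
    }
    inside
  } else {
    (x - prim$center[1])^2 + (y - prim$center[2])^2 +
      (z - prim$center[3])^2 <= (prim$diameter / 2)^2
  }
}

#' Material at a point of a scene
#'
#' Returns the material governing each query point: the highest-priority
#' primitive containing it, the support inside the support slab, or vacuum.
#'
#' @param scene An [specimen_scene()].
#' @param x,y,z Coordinates in nm (vectorized).
#' @return Character vector of material names (`"vacuum"` where none).
#' @export
material_at <- function(scene, x, y, z) {
  idx <- material_index_at(scene, x, y, z)
  nms <- c("vacuum", scene$support$name,
           map_chr_(scene$primitives, function(p) p$material$name))
  nms[idx + 2L]
}

# -1 vacuum, 0 support, i >= 1 primitive i (highest priority wins)
material_index_at <- function(scene, x, y, z) {
  out <- rep.int(-1L, length(x))
  out[z >= 0 & z < scene$support_thickness] <- 0L
  for (i in seq_along(scene$primitives)) {
    out[prim_contains(scene$primitives[[i]], x, y, z)] <- i
  }
  out
}

# topmost material index for a lateral position (SE proxy); -1 if bare window
topmost_index_at <- function(scene, x, y) {
  ztop <- rep.int(-Inf, length(x))
  out <- rep.int(0L, length(x))
  ztop[] <- scene$support_thickness
  for (i in seq_along(scene$primitives)) {
    p <- scene$primitives[[i]]
    if (p$type %in% c("slab", "holed_slab")) {
      hit <- prim_contains(p, x, y, rep((p$z0 + p$z1) / 2, length(x)))
      top <- p$z1
      upd <- hit & top >= ztop
      ztop[upd] <- top; out[upd] <- i
    } else {
      r <- p$diameter / 2
      d2 <- (x - p$center[1])^2 + (y - p$center[2])^2
      hit <- d2 <= r^2
      top <- p$center[3] + sqrt(pmax(r^2 - d2, 0))
      upd <- hit & top >= ztop
      ztop[upd] <- top[upd]; out[upd] <- i
    }
  }
  out
}

scene_top <- function(scene) {
  tops <- c(scene$support_thickness,
            map_dbl(scene$primitives, function(p)
              if (p$type == "sphere") p$center[3] + p$diameter / 2 else p$z1))
  max(tops)
}

scene_materials <- function(scene) {
  mats <- c(list(scene$support), lapply(scene$primitives, function(p) p$material))
  mats[!duplicated(map_chr_(mats, function(m) m$name))]
}

#' Scene presets for the four DNA origami structure classes
#'
#' Builds the specimen scenes of the study's designs on a 3 nm carbon film:
#' `"sdn"` a single 59.2 x 28.5 x 7.4 nm DNA slab, `"ddn"` two stacked slabs
#' (14.8 nm), `"nshdn"` the slab with a 15.6 x 14.2 nm central through-hole,
#' and `"hdn"` the holed slab carrying a 16 nm gold sphere centered on the
#' hole and resting on the support.
#'
#' @param class One of `"sdn"`, `"ddn"`, `"nshdn"`, `"hdn"`.
#' @param orientation_deg In-plane rotation of the structure.
#' @param bounds Lateral window, nm.
#' @return An `lv_scene`.
#' @examples
#' scene_preset("hdn")
#' @export
scene_preset <- function(class = c("sdn", "ddn", "nshdn", "hdn"),
                         orientation_deg = 0, bounds = c(-40, 40, -30, 30)) {
  class <- match.arg(class)
  tpl <- structure_template(class, orientation = orientation_deg)
  template_to_scene(tpl, bounds = bounds)
}

#' Read / write a scene description file
#'
#' Scenes serialize to a YAML list of primitives plus the support definition.
#'
#' @param scene An `lv_scene`.
#' @param file Path.
#' @return `read_scene()` returns an `lv_scene`; `write_scene()` the path,
#'   invisibly.
#' @export
write_scene <- function(scene, file) {
  prims <- lapply(scene$primitives, function(p) {
    out <- p[setdiff(names(p), "material")]
    out$material <- p$material$name
    out
  })
  yaml::write_yaml(list(
    support = list(material = scene$support$name,
                   thickness = scene$support_thickness),
    bounds = as.numeric(scene$bounds), primitives = prims), file)
  invisible(file)
}

#' @rdname write_scene
#' @export
read_scene <- function(file) {
  s <- yaml::read_yaml(file)
  prims <- lapply(s$primitives, function(p) {
    mat <- as_material(p$material)
    switch(p$type,
      slab = prim_slab(unlist(p$center), p$length, p$width, p$orientation,
                       p$z0, p$z1, mat),
      holed_slab = prim_holed_slab(unlist(p$center), p$length, p$width,
                                   p$orientation, p$z0, p$z1,
                                   p$hole_length, p$hole_width, mat),
      sphere = prim_sphere(unlist(p$center), p$diameter, mat),
      abort(sprintf("Unknown primitive type '%s'.", p$type)))
  })
  specimen_scene(prims, bounds = unlist(s$bounds),
                 support_material = s$support$material,
                 support_thickness = s$support$thickness)
}
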