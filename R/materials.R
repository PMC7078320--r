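#' Element record
#'
#' @param symbol Element symbol.
#' @param Z Atomic number (>= 1).
#' @param A Atomic mass, g/mol.
#' @return A one-row tibble.
#' @export
element_record <- function(symbol, Z, A) {
  if (Z < 1) abort("Atomic number must be >= 1.")
  if (A <= Z * 0.9) abort("Atomic mass inconsistent with atomic number.")
  tibble(symbol = symbol, Z = as.numeric(Z), A = as.numeric(A))
}

.elements <- list(
  H = c(1, 1.008), C = c(6, 12.011), N = c(7, 14.007),
  O = c(8, 15.999), P = c(15, 30.974), Au = c(79, 196.967)
)

lookup_element <- function(symbol) {
  e <- .elements[[symbol]]
  if (is.null(e)) abort(sprintf("Unknown element symbol '%s'.", symbol))
  element_record(symbol, e[1], e[2])
}

#' Specimen material
#'
#' A material is a set of elements with atom fractions and a mass density.
#' Atom fractions must sum to 1.
#'
#' @param name Label.
#' @param composition Named numeric vector of atom fractions, names are
#'   element symbols (e.g. `c(C = 1)`), or a tibble with columns
#'   `symbol`, `Z`, `A`, `fraction`.
#' @param density Mass density, g/cm^3 (> 0).
#' @return An `lv_material` object.
#' @examples
#' material("carbon", c(C = 1), density = 2.0)
#' @export
material <- function(name, composition, density) {
  if (!is.numeric(density) || density <= 0) abort("`density` must be > 0.")
  if (is.numeric(composition)) {
    if (is.null(names(composition))) abort("`composition` must be named by element symbol.")
    comp <- bind_rows(lapply(names(composition), lookup_element))
    comp$fraction <- as.numeric(composition)
  } else if (is.data.frame(composition)) {
    comp <- as_tibble(composition)
  } else {
    abort("`composition` must be a named numeric vector or a data frame.")
  }
  if (nrow(comp) == 0) abort("Material composition is empty.")
  if (abs(sum(comp$fraction) - 1) > 1e-9) abort("Atom fractions must sum to 1.")
  structure(list(name = name, composition = comp, density = density),
            class = "lv_material")
}

#' @export
print.lv_material <- function(x, ...) {
  cat(sprintf("<lv_material> %s (rho = %g g/cm^3): %s\n", x$name, x$density,
              paste(sprintf("%s %.3f", x$composition$symbol, x$composition$fraction),
                    collapse = ", ")))
  invisible(x)
}

# atom-fraction weighted atomic mass, g/mol
material_mean_mass <- function(m) sum(m$composition$fraction * m$composition$A)

# atom number density, atoms/nm^3
material_number_density <- function(m) {
  m$density * .const$Na / material_mean_mass(m) * 1e-21
}

#' Built-in material library
#'
#' Reads the material definitions shipped with the package (or a user file of
#' the same YAML layout): DNA as the average monophosphate-nucleotide
#' stoichiometry C9.75 H12.25 N3.75 O7 P at 1.70 g/cm^3, amorphous carbon at
#' 2.0 g/cm^3, and gold at 19.3 g/cm^3.
#'
#' @param file Optional path to a YAML material file; defaults to the
#'   library shipped in `inst/extdata/materials.yaml`.
#' @return Named list of `lv_material` objects.
#' @examples
#' mats <- material_library()
#' names(mats)
#' @export
material_library <- function(file = NULL) {
  file <- file %||% system.file("extdata", "materials.yaml", package = "lvstem")
  spec <- yaml::read_yaml(file)
  out <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    fr <- unlist(s$composition)
    material(nm, fr / sum(fr), s$density)
  })
  setNames(out, names(spec))
}

as_material <- function(x) {
  if (inherits(x, "lv_material")) return(x)
  if (is.character(x) && length(x) == 1) {
    lib <- material_library()
    if (!x %in% names(lib)) {
      abort(sprintf("Unknown material '%s'; library has: %s.",
                    x, paste(names(lib), collapse = ", ")))
    }
    return(lib[[x]])
  }
  abort("Expected an lv_material or a library material name.")
}
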