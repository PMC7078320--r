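#' STEM image container
#'
#' A pixel raster with physical calibration. Pixels are stored as a numeric
#' `ny x nx` matrix, row-major with origin top-left (row 1 is the top image
#' row); physical lengths are pixel counts times `pixel_size`. Images can
#' carry a raw count form and an 8-bit display form related by the recorded
#' linear `gain`/`offset`.
#'
#' @param pixels Numeric matrix (counts or 8-bit values).
#' @param pixel_size nm per pixel (> 0).
#' @param channel `"DF"` or `"SE"`.
#' @param display Optional 8-bit matrix in `[0, 255]`.
#' @param gain,offset Linear map `display = pixels * gain + offset`.
#' @param provenance List of generator parameters and seed; for synthetic
#'   images it fully determines the pixel data.
#' @return An `lv_stem_image`.
#' @export
stem_image <- function(pixels, pixel_size, channel = c("DF", "SE"),
                       display = NULL, gain = NA_real_, offset = 0,
                       provenance = list()) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels)) abort("`pixels` must be a matrix.")
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  if (!is.null(display) && (min(display) < 0 || max(display) > 255)) {
    abort("8-bit display values must lie in [0, 255].")
  }
  structure(list(pixels = pixels, pixel_size = pixel_size, channel = channel,
                 display = display, gain = gain, offset = offset,
                 provenance = provenance),
            class = "lv_stem_image")
}

#' @export
print.lv_stem_image <- function(x, ...) {
  cat(sprintf("<lv_stem_image> %s %d x %d px @ %g nm/px, range [%g, %g]\n",
              x$channel, ncol(x$pixels), nrow(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# measurement values: 8-bit display when present, else raw counts
image_values <- function(image) image$display %||% image$pixels

#' @export
dim.lv_stem_image <- function(x) dim(x$pixels)

#' @export
as_tibble.lv_stem_image <- function(x, ...) {
  px <- image_values(x)
  tibble(
    row = rep(seq_len(nrow(px)), times = ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    x = (rep(seq_len(ncol(px)), each = nrow(px)) - 1) * x$pixel_size,
    y = (rep(seq_len(nrow(px)), times = ncol(px)) - 1) * x$pixel_size,
    value = as.numeric(px)
  )
}

#' @export
autoplot.lv_stem_image <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = -.data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = object$channel)
}

#' Write / read STEM images
#'
#' `write_stem_image()` writes the 8-bit display form (PNG or 8-bit TIFF) or
#' the raw counts (16-bit TIFF) with a YAML sidecar recording calibration and
#' provenance; `read_stem_image()` reads either back (sidecar optional).
#'
#' @param image An `lv_stem_image`.
#' @param path Output path; format from extension (`.png` or `.tif`/`.tiff`).
#' @param what `"display"` (8-bit) or `"counts"` (16-bit TIFF).
#' @param sidecar Write `<path>.yaml` with pixel size, channel, gain/offset
#'   and scalar provenance fields.
#' @return The path, invisibly; `read_stem_image()` returns an
#'   `lv_stem_image`.
#' @export
write_stem_image <- function(image, path, what = c("display", "counts"),
                             sidecar = TRUE) {
  what <- match.arg(what)
  ext <- tolower(tools::file_ext(path))
  if (what == "display") {
    px <- image$display
    if (is.null(px)) {
      sc <- quantize_8bit(image$pixels)
      px <- sc$display
    }
    arr <- px / 255
    if (ext == "png") png::writePNG(arr, path)
    else tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else {
    if (ext == "png") abort("Counts are written as 16-bit TIFF, not PNG.")
    mx <- max(image$pixels, 1)
    tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L)
    if (mx > 65535) warn("Counts exceed 16-bit range; clipped.")
  }
  if (sidecar) {
    prov <- image$provenance
    prov <- prov[vapply(prov, function(v) is.atomic(v) && length(v) <= 8,
                        logical(1))]
    yaml::write_yaml(list(pixel_size = image$pixel_size,
                          channel = image$channel, gain = image$gain,
                          offset = image$offset, provenance = prov),
                     paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_stem_image
#' @export
read_stem_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") round(png::readPNG(path) * 255)
         else tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  meta <- list(pixel_size = 1, channel = "DF", gain = NA_real_, offset = 0)
  side <- paste0(path, ".yaml")
  if (file.exists(side)) meta <- modifyList(meta, yaml::read_yaml(side))
  is8 <- max(arr) <= 255
  stem_image(arr, pixel_size = meta$pixel_size,
             channel = if (identical(meta$channel, "SE")) "SE" else "DF",
             display = if (is8) arr else NULL, gain = meta$gain %||% NA_real_,
             offset = meta$offset %||% 0,
             provenance = meta$provenance %||% list())
}

# linear 8-bit quantization with recorded gain (offset fixed at 0 so Eq.-1
# contrast is preserved)
quantize_8bit <- function(counts, gain = NULL) {
  gain <- gain %||% (255 / max(counts, 1))
  display <- round(counts * gain)
  display[display < 0] <- 0
  display[display > 255] <- 255
  list(display = display, gain = gain, offset = 0)
}
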