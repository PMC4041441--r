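#' Construct a gel image
#'
#' A gel image is a nonnegative intensity matrix with row 1 at the well side
#' of the gel (migration increases with row index) and high values meaning
#' signal. Scans that violate either convention are normalized at read time
#' via `invert`/`flip` (see [read_gel_image()]).
#'
#' @param pixels Numeric matrix of nonnegative intensities, at least
#'   50 rows x 20 columns.
#' @param bit_depth Nominal scan bit depth (8 or 16); informational.
#' @return A `gel_image` object.
#' @export
gel_image <- function(pixels, bit_depth = 16) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix", class = "telka_error_image")
  }
  if (nrow(pixels) < 50 || ncol(pixels) < 20) {
    abort("gel images must be at least 50 rows x 20 columns",
          class = "telka_error_image")
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    abort("gel intensities must be finite and nonnegative",
          class = "telka_error_image")
  }
  if (!bit_depth %in% c(8, 16)) {
    abort("`bit_depth` must be 8 or 16", class = "telka_error_image")
  }
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth)),
            class = "gel_image")
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("<gel_image> %d rows x %d cols, %d-bit, intensity [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gel_image <- function(x) dim(x$pixels)

#' Read a blot scan from TIFF or PNG
#'
#' Grayscale 8- or 16-bit TIFF and PNG are supported; RGB input is collapsed
#' to luminance with a warning. Intensities are returned on the `[0, 1]`
#' scale of the underlying reader.
#'
#' @param path Image file path (`.tif`, `.tiff` or `.png`).
#' @param invert Set `TRUE` for film scans where signal is dark: intensities
#'   are flipped to `max - x` so that high values mean signal.
#' @param flip Set `TRUE` when the wells are at the bottom edge of the scan:
#'   rows are reversed so migration increases with row index.
#' @return A [gel_image()].
#' @export
read_gel_image <- function(path, invert = FALSE, flip = FALSE) {
  if (!file.exists(path)) {
    abort(glue::glue("image file not found: {path}"), class = "telka_error_io")
  }
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
      tif = ,
      tiff = tiff::readTIFF(path),
      png = png::readPNG(path),
      abort(glue::glue(
        "unsupported image format '.{ext}': supported formats are ",
        "TIFF (.tif/.tiff) and PNG (.png)"), class = "telka_error_io")
    ),
    error = function(e) {
      if (inherits(e, "telka_error_io")) stop(e)
      abort(glue::glue("failed to read image '{path}': {conditionMessage(e)}"),
            class = "telka_error_io")
    }
  )
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3]
    warn("multi-channel image collapsed to luminance",
         class = "telka_warning_rgb")
    px <- if (nch >= 3) {
      0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
    } else {
      px[, , 1]
    }
  }
  if (invert) px <- max(px) - px
  if (flip) px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
  gel_image(px, bit_depth = 16)
}

#' Write a gel image to TIFF or PNG
#'
#' Intensities are clipped to `[0, 1]` and stored at the requested bit depth.
#'
#' @param image A [gel_image()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_gel_image <- function(image, path) {
  stopifnot(inherits(image, "gel_image"))
  px <- pmin(pmax(image$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  bps <- image$bit_depth
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = bps),
    png = png::writePNG(px, path),
    abort(glue::glue(
      "unsupported image format '.{ext}': supported formats are ",
      "TIFF (.tif/.tiff) and PNG (.png)"), class = "telka_error_io")
  )
  invisible(path)
}
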