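#' RGB image container
#'
#' Pixels are stored as an `H x W x 3` array of red/green/blue intensities on
#' `[0, 1]`, together with the bit depth of the source file so values can be
#' written back on the original integer scale.
#'
#' @param pixels Numeric `H x W x 3` array with values in `[0, 1]`.
#' @param bit_depth Source bit depth, 8 or 16.
#' @param id Free-text image identifier.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, bit_depth = 8L, id = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  d <- dim(pixels)
  if (d[3] != 3L) {
    stop(sprintf("image must have exactly 3 channels, got %d", d[3]),
         call. = FALSE)
  }
  if (d[1] < 1L || d[2] < 1L) stop("image must be at least 1 x 1", call. = FALSE)
  if (!all(is.finite(pixels))) stop("pixel values must be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         id = as.character(id)),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %s: %d x %d, %d-bit source\n",
              if (nzchar(x$id)) x$id else "(unnamed)", d[1], d[2], x$bit_depth))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Read a PNG or TIFF image
#'
#' Reads an 8- or 16-bit RGB image and scales intensities to `[0, 1]` by
#' dividing by `2^depth - 1`. An alpha channel is dropped with a warning;
#' single- or two-channel images are rejected.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param id Identifier stored on the image; defaults to the file name.
#' @return An [rgb_image].
#' @export
read_image <- function(path, id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    depth <- attr(x, "info")$bit.depth %||% 8L
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(x, "bits.per.sample") %||% 8L
  } else {
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  }
  if (is.null(dim(x)) || length(dim(x)) == 2L) {
    stop("image has 1 channel; 3-channel RGB required", call. = FALSE)
  }
  nc <- dim(x)[3]
  if (nc == 2L) {
    stop("image has 2 channels; 3-channel RGB required", call. = FALSE)
  }
  if (nc == 4L) {
    warning("alpha channel dropped", call. = FALSE)
    x <- x[, , 1:3, drop = FALSE]
  } else if (nc != 3L) {
    stop(sprintf("image has %d channels; 3-channel RGB required", nc),
         call. = FALSE)
  }
  # readPNG/readTIFF already divide by 2^depth - 1; drop reader metadata
  x <- array(as.numeric(x), dim = dim(x))
  rgb_image(x, bit_depth = depth, id = id %||% basename(path))
}

#' Write an image as PNG or TIFF
#'
#' Values are quantized as `round(v * (2^depth - 1))` with halves rounded
#' away from zero, so a write/read round trip at matching depth is
#' bit-exact. The format follows the file extension. 16-bit output is
#' available for TIFF; PNG output is 8-bit.
#'
#' @param image An [rgb_image].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param depth Output bit depth, 8 or 16.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path, depth = image$bit_depth) {
  stopifnot(inherits(image, "rgb_image"))
  if (!depth %in% c(8, 16)) stop("`depth` must be 8 or 16", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  maxv <- 2^depth - 1
  # pre-quantize, then nudge by ~half an LSB so the writers' rounding
  # (writePNG rounds, writeTIFF truncates) lands on the intended integer
  k <- round_half_away(image$pixels * maxv)
  v <- pmin((k + 0.49) / maxv, 1)
  if (ext == "png") {
    if (depth == 16) {
      stop("16-bit PNG output is not supported; write a TIFF instead",
           call. = FALSE)
    }
    ok <- tryCatch({ png::writePNG(v, target = path); TRUE },
                   error = function(e) e)
  } else if (ext %in% c("tif", "tiff")) {
    ok <- tryCatch({
      tiff::writeTIFF(v, where = path, bits.per.sample = as.integer(depth))
      TRUE
    }, error = function(e) e)
  } else {
    stop(sprintf("unsupported output format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  }
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write image to %s: %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}
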