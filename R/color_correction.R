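#' Color card reference values
#'
#' Holds the ordered patch names and reference sRGB triples (on `[0, 1]`)
#' of a color reference card, e.g. the 24-patch ColorChecker Classic.
#'
#' @param patch_names Character vector of patch names.
#' @param reference_rgb Numeric matrix, one row per patch, columns R, G, B
#'   on `[0, 1]`.
#' @return An object of class `color_card_reference`.
#' @export
color_card_reference <- function(patch_names, reference_rgb) {
  reference_rgb <- as_rgb_matrix(reference_rgb, "reference_rgb")
  if (length(patch_names) != nrow(reference_rgb)) {
    stop("`patch_names` and `reference_rgb` lengths differ", call. = FALSE)
  }
  if (nrow(reference_rgb) < 4L) {
    stop("a color card needs at least 4 patches", call. = FALSE)
  }
  if (min(reference_rgb) < 0 || max(reference_rgb) > 1) {
    stop("reference values must lie in [0, 1]", call. = FALSE)
  }
  rownames(reference_rgb) <- patch_names
  structure(list(patch_names = as.character(patch_names),
                 reference_rgb = reference_rgb),
            class = "color_card_reference")
}

#' Bundled ColorChecker Classic reference
#'
#' The 24-patch X-Rite ColorChecker Classic with its commonly published
#' sRGB coordinates.
#'
#' @return A [color_card_reference].
#' @export
colorchecker_classic <- function() {
  f <- system.file("extdata", "colorchecker_classic_srgb.csv",
                   package = "grapecolor", mustWork = TRUE)
  read_card_reference(f)
}

#' Read a card reference table
#'
#' Delimited text with columns `patch_name, R, G, B`, channel values on
#' the 0-255 scale.
#'
#' @param path File path.
#' @return A [color_card_reference].
#' @export
read_card_reference <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patch_name", "R", "G", "B")
  if (!all(need %in% names(d))) {
    stop("card reference needs columns patch_name, R, G, B", call. = FALSE)
  }
  color_card_reference(d$patch_name, as.matrix(d[, c("R", "G", "B")]) / 255)
}

#' Read patch box definitions
#'
#' Delimited text with columns `patch_name, x0, y0, x1, y1`: 0-based pixel
#' coordinates, boxes half-open `[x0, x1) x [y0, y1)` with x = column and
#' y = row.
#'
#' @param path File path.
#' @return A data frame of boxes.
#' @export
read_patch_boxes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patch_name", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(d))) {
    stop("patch boxes need columns patch_name, x0, y0, x1, y1", call. = FALSE)
  }
  d
}

#' Mean color of rectangular patches
#'
#' @param image An [rgb_image].
#' @param boxes Data frame with columns `x0, y0, x1, y1` (0-based, half-open;
#'   x = column, y = row) and optionally `patch_name`.
#' @return Matrix with one row per box and columns R, G, B.
#' @export
measure_patches <- function(image, boxes) {
  stopifnot(inherits(image, "rgb_image"))
  d <- dim(image$pixels)
  out <- matrix(NA_real_, nrow(boxes), 3L,
                dimnames = list(boxes$patch_name, c("R", "G", "B")))
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    if (b$x0 < 0 || b$y0 < 0 || b$x1 > d[2] || b$y1 > d[1] ||
        b$x0 >= b$x1 || b$y0 >= b$y1) {
      stop(sprintf("patch box %d is empty or outside the image", i),
           call. = FALSE)
    }
    block <- image$pixels[(b$y0 + 1):b$y1, (b$x0 + 1):b$x1, , drop = FALSE]
    out[i, ] <- apply(block, 3L, mean)
  }
  out
}

#' Fit an affine color correction
#'
#' Least-squares affine map (3x3 matrix plus offset) taking measured patch
#' colors to their reference values, fitted in the stored (display-referred)
#' pixel values. The per-channel fit minimizes the summed squared error over
#' patches.
#'
#' @param measured Matrix of measured patch means (rows aligned with the
#'   reference patches), values on `[0, 1]`.
#' @param reference A [color_card_reference] or a matching matrix on `[0, 1]`.
#' @return An object of class `correction_transform` with elements `matrix`
#'   (3x3), `offset` (length 3) and `fit_rmse`.
#' @export
fit_color_correction <- function(measured, reference) {
  measured <- as_rgb_matrix(measured, "measured")
  ref <- if (inherits(reference, "color_card_reference")) {
    reference$reference_rgb
  } else {
    as_rgb_matrix(reference, "reference")
  }
  if (nrow(measured) != nrow(ref)) {
    stop("measured and reference patch counts differ", call. = FALSE)
  }
  if (nrow(measured) < 4L) {
    stop("at least 4 patches are required to fit the correction",
         call. = FALSE)
  }
  X <- cbind(1, measured)
  qx <- qr(X)
  if (qx$rank < 4L) {
    stop("singular fit: patch colors do not span 3 dimensions", call. = FALSE)
  }
  coefs <- qr.coef(qx, ref)            # 4 x 3: intercept then channel weights
  M <- t(coefs[-1L, , drop = FALSE])   # out_channel x in_channel
  offset <- as.numeric(coefs[1L, ])
  pred <- X %*% coefs
  rmse <- sqrt(mean((pred - ref)^2))
  structure(
    list(matrix = unname(M), offset = offset, fit_rmse = rmse),
    class = "correction_transform"
  )
}

#' @export
print.correction_transform <- function(x, ...) {
  cat("<correction_transform> fit RMSE:", format(x$fit_rmse, digits = 4), "\n")
  print(cbind(x$matrix, offset = x$offset))
  invisible(x)
}

#' Apply a color correction to an image
#'
#' Each pixel is mapped as `v' = clip(M v + b, 0, 1)`.
#'
#' @param image An [rgb_image].
#' @param transform A `correction_transform` from [fit_color_correction()].
#' @return The corrected [rgb_image]; `attr(, "color_corrected")` is set.
#' @export
apply_correction <- function(image, transform) {
  stopifnot(inherits(image, "rgb_image"),
            inherits(transform, "correction_transform"))
  d <- dim(image$pixels)
  pm <- matrix(image$pixels, ncol = 3L)          # pixels x channel
  out <- pm %*% t(transform$matrix)
  out <- sweep(out, 2L, transform$offset, "+")
  out <- clip01(out)
  img <- rgb_image(array(out, dim = d), bit_depth = image$bit_depth,
                   id = image$id)
  attr(img, "color_corrected") <- TRUE
  img
}
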