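# Color space conversions and the 11 quantitative color traits.
#
# Traits follow the usual display conventions: R, G, B, intensity and the two
# greyscales on the 0-255 scale, saturation on [0, 1], hue in degrees,
# CIELAB on its native scale. The cluster summary averages berry RGB first
# and converts that mean color (mean-then-convert), which avoids averaging
# hue across the 0/360 wrap.

#' Names of the quantitative color traits
#' @export
COLOR_TRAITS <- c("R", "G", "B", "L", "a", "b", "H", "S", "I",
                  "weighted_grey", "average_grey")

#' RGB to hue/saturation/intensity
#'
#' Uses the arccos (Gonzalez-Woods) hue formulation:
#' `theta = acos(0.5 * ((R-G) + (R-B)) / sqrt((R-G)^2 + (R-B) (G-B)))`,
#' with `H = theta` when `B <= G` and `360 - theta` otherwise. Intensity is
#' the channel mean on the input scale; saturation is `1 - min/I` (0 for
#' black). Achromatic inputs (R = G = B) get `H = 0` and are flagged in the
#' `achromatic` attribute.
#'
#' @param rgb Length-3 vector or `n x 3` matrix on `[0, 1]`.
#' @return Matrix with columns `H` (degrees in `[0, 360)`), `S`, `I`;
#'   attribute `achromatic` is a logical vector.
#' @export
rgb_to_hsi <- function(rgb) {
  m <- as_rgb_matrix(rgb)
  if (!all(is.finite(m)) || min(m) < 0 || max(m) > 1) {
    stop("RGB values must be finite and in [0, 1]", call. = FALSE)
  }
  R <- m[, 1]; G <- m[, 2]; B <- m[, 3]
  I <- (R + G + B) / 3
  mn <- pmin(R, G, B)
  S <- ifelse(I > 0, 1 - mn / I, 0)
  achrom <- (pmax(R, G, B) - mn) < 1e-12
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  theta <- acos(pmin(pmax(ifelse(den > 0, num / den, 1), -1), 1)) * 180 / pi
  H <- ifelse(B <= G, theta, 360 - theta)
  H[achrom] <- 0
  H <- H %% 360
  out <- cbind(H = H, S = S, I = I)
  attr(out, "achromatic") <- achrom
  out
}

# sRGB (IEC 61966-2-1) decoding to linear light
srgb_decode <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

# sRGB D65 primaries -> XYZ (Y of white = 100)
.srgb_to_xyz <- 100 * matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), 3, 3, byrow = TRUE)

.d65_white <- c(X = 95.047, Y = 100.000, Z = 108.883)

#' RGB to CIELAB
#'
#' sRGB decoding (piecewise gamma) to CIE XYZ under D65 / 2 degrees, then
#' CIELAB with the D65 white point (Xn = 95.047, Yn = 100, Zn = 108.883).
#'
#' @param rgb Length-3 vector or `n x 3` matrix on `[0, 1]`.
#' @return Matrix with columns `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(rgb) {
  m <- as_rgb_matrix(rgb)
  if (!all(is.finite(m)) || min(m) < 0 || max(m) > 1) {
    stop("RGB values must be finite and in [0, 1]", call. = FALSE)
  }
  xyz <- srgb_decode(m) %*% t(.srgb_to_xyz)
  tt <- sweep(xyz, 2L, .d65_white, "/")
  delta <- 6 / 29
  f <- ifelse(tt > delta^3, tt^(1 / 3), tt / (3 * delta^2) + 4 / 29)
  L <- 116 * f[, 2] - 16
  a <- 500 * (f[, 1] - f[, 2])
  b <- 200 * (f[, 2] - f[, 3])
  cbind(L = L, a = a, b = b)
}

#' Greyscale values of a color
#'
#' Weighted grey is the relative-luminance combination
#' `0.299 R + 0.587 G + 0.114 B`; average grey is the channel mean.
#'
#' @param rgb Length-3 vector or `n x 3` matrix on the 0-255 scale.
#' @return Matrix with columns `weighted_grey`, `average_grey`.
#' @export
grey_values <- function(rgb) {
  m <- as_rgb_matrix(rgb)
  if (!all(is.finite(m)) || min(m) < 0 || max(m) > 255) {
    stop("RGB values must be finite and in [0, 255]", call. = FALSE)
  }
  cbind(weighted_grey = 0.299 * m[, 1] + 0.587 * m[, 2] + 0.114 * m[, 3],
        average_grey = (m[, 1] + m[, 2] + m[, 3]) / 3)
}

# the 11 traits of a single color given as an RGB triple on [0, 1]
color_traits_from_rgb01 <- function(rgb01) {
  rgb255 <- rgb01 * 255
  hsi <- rgb_to_hsi(rgb01)
  lab <- rgb_to_lab(rgb01)
  avg <- (rgb255[1] + rgb255[2] + rgb255[3]) / 3   # I and average grey alike
  out <- data.frame(
    R = rgb255[1], G = rgb255[2], B = rgb255[3],
    L = lab[1, "L"], a = lab[1, "a"], b = lab[1, "b"],
    H = hsi[1, "H"], S = hsi[1, "S"], I = avg,
    weighted_grey = 0.299 * rgb255[1] + 0.587 * rgb255[2] + 0.114 * rgb255[3],
    average_grey = avg
  )
  rownames(out) <- NULL
  out
}

#' Color summary of one segmented cluster image
#'
#' Averages RGB over berry-labeled pixels, then derives the remaining traits
#' from that mean color: CIELAB, HSI, weighted and average greyscale. R, G,
#' B, I and the greys are reported on 0-255; S on `[0, 1]`; H in degrees.
#' Intensity and average grey are by construction the same number.
#'
#' @param image An [rgb_image].
#' @param mask A matching [label_mask].
#' @param unit_id Identifier for the summary row; defaults to the image id.
#' @return One-row data frame with `unit_id`, the [COLOR_TRAITS] columns and
#'   `n_berry_pixels`.
#' @export
summarize_cluster <- function(image, mask, unit_id = image$id) {
  stopifnot(inherits(image, "rgb_image"), inherits(mask, "label_mask"))
  if (!all(dim(mask$labels) == dim(image$pixels)[1:2])) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  berry <- mask$labels == 1L
  n <- sum(berry)
  if (n == 0L) {
    stop("no berry pixels in mask: cannot summarize cluster color",
         call. = FALSE)
  }
  pm <- matrix(image$pixels, ncol = 3L)
  mean_rgb01 <- colMeans(pm[as.vector(berry), , drop = FALSE])
  out <- color_traits_from_rgb01(mean_rgb01)
  cbind(data.frame(unit_id = unit_id), out,
        data.frame(n_berry_pixels = n))
}

#' Average image summaries to one genotype value
#'
#' Arithmetic mean of each trait over the supplied image summaries (hue
#' included arithmetically); berry pixel counts are summed.
#'
#' @param summaries Data frame of [summarize_cluster()] rows, or a list of
#'   them.
#' @param unit_id Identifier for the aggregated row.
#' @return One-row data frame in the same layout.
#' @export
aggregate_genotype <- function(summaries, unit_id = NULL) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, summaries)
  }
  if (is.null(summaries) || nrow(summaries) == 0L) {
    stop("no summaries to aggregate", call. = FALSE)
  }
  out <- as.data.frame(as.list(colMeans(summaries[, COLOR_TRAITS])))
  names(out) <- COLOR_TRAITS
  cbind(data.frame(unit_id = unit_id %||% summaries$unit_id[1]), out,
        data.frame(n_berry_pixels = sum(summaries$n_berry_pixels)))
}
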