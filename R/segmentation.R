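# Supervised berry/rachis/background segmentation.
#
# The classifier is a nearest-prototype rule in RGB: each user-picked 3x3
# patch contributes one prototype (its mean color) and every pixel takes the
# label of the closest prototype by Euclidean distance. Distance ties are
# broken by class priority berry > rachis > background, then by patch
# insertion order.

#' Segmentation class labels
#'
#' The fixed label set, in tie-break priority order.
#' @export
SEGMENT_CLASSES <- c("berry", "rachis", "background")

#' Label mask
#'
#' A per-pixel labeling over the classes in [SEGMENT_CLASSES], stored as an
#' integer matrix (1 = berry, 2 = rachis, 3 = background).
#'
#' @param labels Integer `H x W` matrix with values in `1:3`, or a character
#'   matrix over [SEGMENT_CLASSES].
#' @param image_id Identifier of the labeled image.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, image_id = "") {
  if (is.character(labels)) {
    m <- match(labels, SEGMENT_CLASSES)
    if (anyNA(m)) stop("unknown class label in mask", call. = FALSE)
    labels <- matrix(m, nrow(labels), ncol(labels))
  }
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || min(labels) < 1L || max(labels) > 3L) {
    stop("mask labels must all be in 1:3 (berry, rachis, background)",
         call. = FALSE)
  }
  structure(list(labels = labels, levels = SEGMENT_CLASSES,
                 image_id = as.character(image_id)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- tabulate(x$labels, 3L)
  cat(sprintf("<label_mask> %d x %d: berry %d, rachis %d, background %d\n",
              nrow(x$labels), ncol(x$labels), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Build a training set from picked pixels
#'
#' Each pick marks the center of a 3x3 block; the block's mean RGB becomes
#' one class prototype. All three classes must be represented; several picks
#' per class are allowed and give multi-prototype classes.
#'
#' @param image An [rgb_image].
#' @param picks Data frame with columns `row`, `col` (0-based pixel
#'   coordinates of the block center) and `label` (one of [SEGMENT_CLASSES]).
#' @return An object of class `training_set`.
#' @export
build_training_set <- function(image, picks) {
  stopifnot(inherits(image, "rgb_image"))
  need <- c("row", "col", "label")
  if (!all(need %in% names(picks))) {
    stop("`picks` needs columns row, col, label", call. = FALSE)
  }
  bad <- setdiff(unique(picks$label), SEGMENT_CLASSES)
  if (length(bad)) {
    stop(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(SEGMENT_CLASSES, picks$label)
  if (length(missing)) {
    stop(sprintf("incomplete training set: no pick for class(es) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  d <- dim(image$pixels)
  patches <- vector("list", nrow(picks))
  for (i in seq_len(nrow(picks))) {
    r <- picks$row[i]; cc <- picks$col[i]
    if (r < 1 || cc < 1 || r > d[1] - 2 || cc > d[2] - 2) {
      stop(sprintf("pick %d: 3x3 block around (%d, %d) is outside the image",
                   i, r, cc), call. = FALSE)
    }
    block <- image$pixels[r:(r + 2), cc:(cc + 2), , drop = FALSE]
    cols <- matrix(block, ncol = 3L)
    patches[[i]] <- list(
      label = picks$label[i],
      center = c(row = r, col = cc),
      pixel_colors = cols,
      prototype = colMeans(cols)
    )
  }
  structure(list(patches = patches, source_image_id = image$id),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  labs <- vapply(x$patches, `[[`, "", "label")
  cat(sprintf("<training_set> %d prototypes (%s) from image '%s'\n",
              length(labs),
              paste(sprintf("%s: %d", SEGMENT_CLASSES,
                            tabulate(match(labs, SEGMENT_CLASSES), 3L)),
                    collapse = ", "),
              x$source_image_id))
  invisible(x)
}

# prototypes ordered by (class priority, insertion order); with
# max.col(ties = "first") this realizes the documented tie-break
prototype_table <- function(ts) {
  labs <- vapply(ts$patches, `[[`, "", "label")
  proto <- do.call(rbind, lapply(ts$patches, `[[`, "prototype"))
  ord <- order(match(labs, SEGMENT_CLASSES), seq_along(labs))
  list(proto = proto[ord, , drop = FALSE],
       class_idx = match(labs, SEGMENT_CLASSES)[ord])
}

#' Segment an image with a training set
#'
#' Assigns every pixel the label of its nearest prototype (Euclidean
#' distance in RGB). Deterministic for fixed inputs.
#'
#' @param image An [rgb_image].
#' @param ts A [build_training_set()] result.
#' @return A [label_mask].
#' @export
segment_image <- function(image, ts) {
  stopifnot(inherits(image, "rgb_image"), inherits(ts, "training_set"))
  pt <- prototype_table(ts)
  pm <- matrix(image$pixels, ncol = 3L)
  k <- nrow(pt$proto)
  d2 <- matrix(0, nrow(pm), k)
  for (j in seq_len(k)) {
    d2[, j] <- (pm[, 1] - pt$proto[j, 1])^2 +
               (pm[, 2] - pt$proto[j, 2])^2 +
               (pm[, 3] - pt$proto[j, 3])^2
  }
  nearest <- max.col(-d2, ties.method = "first")
  labels <- matrix(pt$class_idx[nearest], dim(image$pixels)[1],
                   dim(image$pixels)[2])
  label_mask(labels, image_id = image$id)
}

#' Export a segmented image
#'
#' Writes the segmentation as a 24-bit (8-bit per channel) PNG: berry and
#' rachis pixels keep their colors, background pixels become pure white.
#' Optionally writes a companion single-channel PNG holding the raw labels,
#' which [read_label_mask()] round-trips.
#'
#' @param image An [rgb_image].
#' @param mask A matching [label_mask].
#' @param path Output PNG path for the visual segmentation.
#' @param labels_path Optional output PNG path for the raw labels.
#' @return Invisibly, `path`.
#' @export
export_segmented <- function(image, mask, path, labels_path = NULL) {
  stopifnot(inherits(image, "rgb_image"), inherits(mask, "label_mask"))
  d <- dim(image$pixels)
  if (!all(dim(mask$labels) == d[1:2])) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  px <- image$pixels
  bg <- mask$labels == 3L
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[bg] <- 1
    px[, , ch] <- plane
  }
  write_image(rgb_image(px, bit_depth = 8L, id = image$id), path, depth = 8)
  if (!is.null(labels_path)) {
    png::writePNG(mask$labels / 255, target = labels_path)
  }
  invisible(path)
}

#' Read a label PNG back into a mask
#'
#' @param path Label PNG written by [export_segmented()].
#' @param image_id Identifier to attach.
#' @return A [label_mask].
#' @export
read_label_mask <- function(path, image_id = "") {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  label_mask(matrix(as.integer(round(x * 255)), nrow(x), ncol(x)),
             image_id = image_id)
}

# logical matrix: TRUE where the full 3x3 neighborhood shares the pixel's
# class; image borders are FALSE
interior_pixels <- function(mask) {
  m <- mask$labels
  H <- nrow(m); W <- ncol(m)
  ok <- matrix(FALSE, H, W)
  if (H < 3L || W < 3L) return(ok)
  core <- m[2:(H - 1), 2:(W - 1)]
  agree <- matrix(TRUE, H - 2L, W - 2L)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    agree <- agree & (m[(2 + dr):(H - 1 + dr), (2 + dc):(W - 1 + dc)] == core)
  }
  ok[2:(H - 1), 2:(W - 1)] <- agree
  ok
}

#' Segmentation accuracy against a reference mask
#'
#' Confusion-matrix metrics of a predicted mask against ground truth:
#' overall pixel accuracy plus per-class precision and recall. Classes
#' absent from the truth get `NA` (undefined), not zero. With
#' `interior_only = TRUE` only pixels whose full 3x3 truth neighborhood is
#' single-class are scored, excluding the 1-pixel class boundaries.
#'
#' @param mask Predicted [label_mask].
#' @param truth Reference [label_mask] of the same dimensions.
#' @param interior_only Score only interior (non-boundary) pixels?
#' @return List with `accuracy`, `per_class` (data frame of precision,
#'   recall, truth pixel counts) and the 3x3 `confusion` matrix.
#' @export
evaluate_segmentation <- function(mask, truth, interior_only = FALSE) {
  stopifnot(inherits(mask, "label_mask"), inherits(truth, "label_mask"))
  if (!all(dim(mask$labels) == dim(truth$labels))) {
    stop("mask and truth dimensions differ", call. = FALSE)
  }
  keep <- if (interior_only) interior_pixels(truth) else TRUE
  p <- factor(mask$labels[keep], levels = 1:3, labels = SEGMENT_CLASSES)
  t <- factor(truth$labels[keep], levels = 1:3, labels = SEGMENT_CLASSES)
  conf <- table(truth = t, predicted = p)
  n_truth <- rowSums(conf)
  n_pred <- colSums(conf)
  correct <- diag(conf)
  precision <- ifelse(n_pred > 0, correct / n_pred, NA_real_)
  recall <- ifelse(n_truth > 0, correct / n_truth, NA_real_)
  precision[n_truth == 0] <- NA_real_   # class absent from truth: undefined
  list(
    accuracy = sum(correct) / sum(conf),
    per_class = data.frame(class = SEGMENT_CLASSES,
                           precision = as.numeric(precision),
                           recall = as.numeric(recall),
                           n_truth = as.numeric(n_truth)),
    confusion = conf
  )
}

#' Read training picks from a delimited file
#'
#' Columns `image_id, row, col, label`, 0-based pixel coordinates.
#'
#' @param path File path.
#' @return Data frame of picks.
#' @export
read_picks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("row", "col", "label") %in% names(d))) {
    stop("picks file needs columns row, col, label", call. = FALSE)
  }
  d
}

#' Write or read a training set as delimited text
#'
#' One row per patch: `label, row, col, proto_r, proto_g, proto_b`
#' (prototypes on `[0, 1]`). Reading restores the prototypes, which is all
#' the classifier needs.
#'
#' @param ts A `training_set`.
#' @param path File path.
#' @return `write_training_set` returns `path` invisibly;
#'   `read_training_set` a `training_set`.
#' @export
write_training_set <- function(ts, path) {
  stopifnot(inherits(ts, "training_set"))
  rows <- do.call(rbind, lapply(ts$patches, function(p) {
    data.frame(label = p$label, row = p$center[["row"]],
               col = p$center[["col"]],
               proto_r = p$prototype[1], proto_g = p$prototype[2],
               proto_b = p$prototype[3])
  }))
  utils::write.csv(cbind(source_image_id = ts$source_image_id, rows),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  patches <- lapply(seq_len(nrow(d)), function(i) {
    list(label = d$label[i], center = c(row = d$row[i], col = d$col[i]),
         pixel_colors = NULL,
         prototype = c(d$proto_r[i], d$proto_g[i], d$proto_b[i]))
  })
  structure(list(patches = patches,
                 source_image_id = d$source_image_id[1] %||% ""),
            class = "training_set")
}
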