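# Synthetic cluster images with ground-truth masks.
#
# The renderer is deliberately simple: a white backdrop, a branched rachis
# polyline, and overlapping shaded disks for berries, with per-berry color
# jitter and occasional specular highlights. It emulates the photographic
# setup (suspended cluster, white background) well enough to exercise
# segmentation and color extraction against known truth; it does not model
# 3-D geometry, shadows or lens effects.

#' Specification of a synthetic cluster image
#'
#' @param n_berries Number of berries (>= 1).
#' @param berry_radius `c(mean, jitter)` berry radius in pixels.
#' @param berry_base_rgb Base berry color on `[0, 1]` (default: noir
#'   blue-black).
#' @param color_jitter_sd Per-berry Gaussian color jitter SD per channel.
#' @param highlight_prob Probability a berry carries a specular highlight.
#' @param highlight_gain Fraction of the distance toward white applied in a
#'   highlight.
#' @param shading Radial darkening at the berry rim (0 = flat disks).
#' @param rachis_rgb Rachis (stem) color.
#' @param background_rgb Backdrop color (near-white).
#' @param image_size `c(H, W)` in pixels.
#' @param seed Integer seed; rendering is deterministic given the seed.
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(n_berries = 28, berry_radius = c(11, 2),
                         berry_base_rgb = c(0.10, 0.08, 0.14),
                         color_jitter_sd = 0.02,
                         highlight_prob = 0.25, highlight_gain = 0.35,
                         shading = 0.15,
                         rachis_rgb = c(0.42, 0.26, 0.12),
                         background_rgb = c(0.97, 0.97, 0.95),
                         image_size = c(160, 160), seed = 1) {
  stopifnot(n_berries >= 1, length(berry_radius) == 2,
            length(image_size) == 2)
  for (col in list(berry_base_rgb, rachis_rgb, background_rgb)) {
    if (length(col) != 3 || min(col) < 0 || max(col) > 1) {
      stop("spec colors must be RGB triples on [0, 1]", call. = FALSE)
    }
  }
  structure(list(n_berries = n_berries, berry_radius = berry_radius,
                 berry_base_rgb = berry_base_rgb,
                 color_jitter_sd = color_jitter_sd,
                 highlight_prob = highlight_prob,
                 highlight_gain = highlight_gain, shading = shading,
                 rachis_rgb = rachis_rgb, background_rgb = background_rgb,
                 image_size = image_size, seed = seed),
            class = "cluster_spec")
}

# paint a thick line segment into label/color planes (by reference-ish:
# returns updated list). p0/p1 are c(row, col).
paint_segment <- function(canvas, labels, p0, p1, width, col_rgb, jitter_sd) {
  H <- nrow(labels); W <- ncol(labels)
  len <- sqrt(sum((p1 - p0)^2))
  ts <- seq(0, 1, length.out = max(2L, ceiling(len * 2)))
  pr <- round(p0[1] + ts * (p1[1] - p0[1]))
  pc <- round(p0[2] + ts * (p1[2] - p0[2]))
  half <- floor(width / 2)
  off <- expand.grid(dr = -half:half, dc = -half:half)
  rows <- pmin(pmax(rep(pr, each = nrow(off)) + off$dr, 1L), H)
  cols <- pmin(pmax(rep(pc, each = nrow(off)) + off$dc, 1L), W)
  idx <- unique(cbind(rows, cols))
  lin <- idx[, 1] + (idx[, 2] - 1L) * H
  labels[lin] <- 2L
  for (ch in 1:3) {
    v <- clip01(col_rgb[ch] + stats::rnorm(length(lin), 0, jitter_sd))
    canvas[lin + (ch - 1L) * H * W] <- v
  }
  list(canvas = canvas, labels = labels)
}

#' Render a synthetic grape cluster
#'
#' @param spec A [cluster_spec()].
#' @return List with `image` (an [rgb_image]) and `mask` (the ground-truth
#'   [label_mask]).
#' @export
generate_cluster_image <- function(spec = cluster_spec()) {
  stopifnot(inherits(spec, "cluster_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  rmax <- spec$berry_radius[1] + 3 * abs(spec$berry_radius[2])
  margin <- ceiling(rmax) + 2
  if (2 * margin >= min(H, W)) {
    stop("berries cannot fit: image too small for the berry radius",
         call. = FALSE)
  }
  with_seed(spec$seed, {
    canvas <- array(rep(spec$background_rgb, each = H * W), dim = c(H, W, 3))
    labels <- matrix(3L, H, W)
    # rachis: main stem from the top into the cluster, with short branches
    cx <- W / 2
    stem_end <- c(0.55 * H, cx + stats::rnorm(1, 0, W / 40))
    ps <- paint_segment(canvas, labels, c(2, cx), stem_end, 3,
                        spec$rachis_rgb, 0.015)
    canvas <- ps$canvas; labels <- ps$labels
    n_branch <- 3L
    for (k in seq_len(n_branch)) {
      t0 <- 0.3 + 0.5 * (k - 1) / max(1, n_branch - 1)
      start <- c(2 + t0 * (stem_end[1] - 2), cx + t0 * (stem_end[2] - cx))
      ang <- stats::runif(1, 20, 70) * pi / 180 * sample(c(-1, 1), 1)
      blen <- stats::runif(1, 0.12, 0.2) * min(H, W)
      end <- start + blen * c(cos(ang) * 0.6 + 0.4, sin(ang))
      end <- pmin(pmax(end, margin), c(H, W) - margin)
      ps <- paint_segment(canvas, labels, start, end, 2,
                          spec$rachis_rgb, 0.015)
      canvas <- ps$canvas; labels <- ps$labels
    }
    # berries: shaded disks clustered below the stem
    for (i in seq_len(spec$n_berries)) {
      r <- max(3, stats::rnorm(1, spec$berry_radius[1], spec$berry_radius[2]))
      ctr_r <- stats::runif(1, 0.3 * H, H - margin)
      ctr_c <- min(max(cx + stats::rnorm(1, 0, 0.14 * W), margin + 1),
                   W - margin)
      base <- clip01(spec$berry_base_rgb +
                       stats::rnorm(3, 0, spec$color_jitter_sd))
      rr <- max(1, floor(ctr_r - r)):min(H, ceiling(ctr_r + r))
      cc <- max(1, floor(ctr_c - r)):min(W, ceiling(ctr_c + r))
      dg <- outer((rr - ctr_r)^2, (cc - ctr_c)^2, "+")
      inside <- dg <= r^2
      if (!any(inside)) next
      shade <- 1 - spec$shading * dg / r^2   # mild radial darkening
      hl <- NULL
      if (stats::runif(1) < spec$highlight_prob) {
        hr <- r / 4
        hctr <- c(ctr_r - r / 3, ctr_c - r / 3)
        dh <- outer((rr - hctr[1])^2, (cc - hctr[2])^2, "+")
        hl <- dh <= hr^2
      }
      sub_lab <- labels[rr, cc]
      for (ch in 1:3) {
        plane <- canvas[rr, cc, ch]
        v <- base[ch] * shade
        if (!is.null(hl)) {
          v[hl] <- v[hl] + spec$highlight_gain * (1 - v[hl])
        }
        plane[inside] <- clip01(v[inside])
        canvas[rr, cc, ch] <- plane
      }
      sub_lab[inside] <- 1L
      labels[rr, cc] <- sub_lab
    }
    list(image = rgb_image(canvas, bit_depth = 8L, id = "synthetic"),
         mask = label_mask(labels, image_id = "synthetic"))
  })
}

#' Twelve images of one genotype
#'
#' Renders `n_images` independent synthetic cluster images whose berry base
#' color is the genotype's simulated mean berry RGB, with per-image jitter
#' (emulating three clusters photographed at four rotations).
#'
#' @param cross A simulated [ptcross] whose phenotype table carries R, G, B.
#' @param id Genotype id.
#' @param template A [cluster_spec()] providing geometry and noise settings.
#' @param n_images Images per genotype (default 12).
#' @param seed Integer seed.
#' @return List with `id`, `images` (list of [rgb_image]) and `masks`
#'   (list of [label_mask]).
#' @export
render_genotype <- function(cross, id, template = cluster_spec(),
                            n_images = 12, seed = 1) {
  stopifnot(inherits(cross, "ptcross"))
  row <- match(id, cross$pheno$id)
  if (is.na(row)) stop(sprintf("genotype '%s' not in cross", id), call. = FALSE)
  base <- c(cross$pheno$R[row], cross$pheno$G[row], cross$pheno$B[row]) / 255
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n_images),
    jitter = matrix(stats::rnorm(3 * n_images, 0, template$color_jitter_sd),
                    n_images, 3)))
  images <- vector("list", n_images)
  masks <- vector("list", n_images)
  for (k in seq_len(n_images)) {
    sp <- template
    sp$berry_base_rgb <- clip01(base + draws$jitter[k, ])
    sp$seed <- draws$seeds[k]
    out <- generate_cluster_image(sp)
    out$image$id <- sprintf("%s_img%02d", id, k)
    out$mask$image_id <- out$image$id
    images[[k]] <- out$image
    masks[[k]] <- out$mask
  }
  list(id = id, images = images, masks = masks)
}

#' Render images for a whole population
#'
#' Calls [render_genotype()] for every individual. Note the result holds
#' `n_images` rasters per genotype; for large populations iterate over
#' [render_genotype()] and summarize one genotype at a time instead.
#'
#' @inheritParams render_genotype
#' @return List of [render_genotype()] results, one per individual.
#' @export
render_population <- function(cross, template = cluster_spec(),
                              n_images = 12, seed = 1) {
  stopifnot(inherits(cross, "ptcross"))
  ids <- cross$pheno$id
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(ids)))
  lapply(seq_along(ids), function(i) {
    render_genotype(cross, ids[i], template = template, n_images = n_images,
                    seed = seeds[i])
  })
}

#' Automatic training picks from a ground-truth mask
#'
#' Selects, per class, centers of 3x3 blocks that are uniformly that class
#' in the truth mask: the block closest to the class's mean image color
#' first, then blocks chosen greedily to be maximally far (in RGB) from the
#' already selected ones -- mimicking a user adding extra picks to cover
#' color extremes such as highlights. Deterministic.
#'
#' @param image An [rgb_image].
#' @param mask The ground-truth [label_mask].
#' @param n_per_class Picks per class.
#' @return Data frame `row, col, label` with 0-based block-center
#'   coordinates, as consumed by [build_training_set()].
#' @export
training_picks_from_truth <- function(image, mask, n_per_class = 2) {
  stopifnot(inherits(image, "rgb_image"), inherits(mask, "label_mask"))
  ok <- interior_pixels(mask)
  picks <- list()
  pm <- matrix(image$pixels, ncol = 3L)
  for (cls in 1:3) {
    cand <- which(ok & mask$labels == cls, arr.ind = TRUE)
    if (nrow(cand) == 0L) {
      stop(sprintf("no uniform 3x3 block found for class '%s'",
                   SEGMENT_CLASSES[cls]), call. = FALSE)
    }
    lin <- cand[, 1] + (cand[, 2] - 1L) * nrow(mask$labels)
    cols <- pm[lin, , drop = FALSE]
    mean_col <- colMeans(pm[mask$labels == cls, , drop = FALSE])
    d0 <- rowSums(sweep(cols, 2L, mean_col)^2)
    sel <- which.min(d0)
    while (length(sel) < min(n_per_class, nrow(cand))) {
      dmin <- rep(Inf, nrow(cand))
      for (s in sel) {
        dmin <- pmin(dmin, rowSums(sweep(cols, 2L, cols[s, ])^2))
      }
      dmin[sel] <- -Inf
      sel <- c(sel, which.max(dmin))
    }
    picks[[cls]] <- data.frame(row = cand[sel, 1] - 1L,
                               col = cand[sel, 2] - 1L,
                               label = SEGMENT_CLASSES[cls])
  }
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}
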