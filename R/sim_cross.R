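# Simulated pseudo-testcross populations.
#
# The default scenario mirrors a hybrid wine-grape F1 segregating 1:1 for
# noir/nonnoir fruit: a major binary color locus at 63 cM on maternal
# chromosome 2 (high but imperfect penetrance) plus two minor additive loci
# feeding a latent "darkness" value that drives all color traits.

#' Default simulated parental maps
#'
#' Three 100-cM chromosomes per parental map with markers every 5 cM.
#'
#' @param chromosomes Chromosome names.
#' @param length_cM Chromosome length.
#' @param spacing_cM Marker spacing.
#' @return Map data frame (`marker`, `chr`, `pos`, `parent`).
#' @export
default_sim_maps <- function(chromosomes = c("1", "2", "3"),
                             length_cM = 100, spacing_cM = 5) {
  do.call(rbind, lapply(PARENTAL_MAPS, function(par) {
    do.call(rbind, lapply(chromosomes, function(ch) {
      pos <- seq(0, length_cM, by = spacing_cM)
      data.frame(
        marker = sprintf("%s%s_%03d", substr(par, 1, 3), ch, seq_along(pos)),
        chr = ch, pos = pos, parent = par, stringsAsFactors = FALSE)
    }))
  }))
}

#' Specification of a simulated cross
#'
#' Defaults reproduce the study-like design: 110 individuals, a major
#' binary noir locus at 63 cM on maternal chromosome 2 with penetrance
#' 0.98, two minor additive loci (effect 0.12 on the latent darkness
#' scale), residual SD 0.117 -- the major locus then explains about 75% of
#' the latent variance -- and 5% missing genotypes.
#'
#' @param n_individuals Population size.
#' @param maps Map data frame as from [default_sim_maps()].
#' @param qtl List of QTL, each `list(chr, pos, parent, type, effect)` with
#'   `type` one of `"binary-major"`, `"additive-minor"`.
#' @param residual_sd Residual SD of the latent darkness value.
#' @param penetrance P(noir | B allele at the major locus).
#' @param missing_rate Fraction of genotypes masked as missing.
#' @param seed Integer seed; simulation is deterministic given the seed.
#' @return An object of class `sim_cross_spec`.
#' @export
sim_cross_spec <- function(n_individuals = 110,
                           maps = default_sim_maps(),
                           qtl = list(
                             list(chr = "2", pos = 63, parent = "maternal",
                                  type = "binary-major", effect = 0.5),
                             list(chr = "3", pos = 30, parent = "maternal",
                                  type = "additive-minor", effect = 0.12),
                             list(chr = "1", pos = 50, parent = "paternal",
                                  type = "additive-minor", effect = 0.12)),
                           residual_sd = 0.117, penetrance = 0.98,
                           missing_rate = 0.05, seed = 1) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  for (q in qtl) {
    sel <- maps$parent == q$parent & maps$chr == q$chr
    if (!any(sel)) stop("QTL chromosome not in map", call. = FALSE)
    if (q$pos < min(maps$pos[sel]) || q$pos > max(maps$pos[sel])) {
      stop("QTL position outside its chromosome", call. = FALSE)
    }
  }
  structure(list(n_individuals = n_individuals, maps = maps, qtl = qtl,
                 residual_sd = residual_sd, penetrance = penetrance,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_cross_spec")
}

# representative berry colors along a latent darkness axis, anchored to the
# OIV 225 narrative (green-yellow -> rose -> red -> dark violet -> blue-black)
.darkness_anchors <- list(
  d = c(0, 0.33, 0.55, 0.8, 1),
  rgb = rbind(c(0.65, 0.70, 0.30),
              c(0.75, 0.45, 0.45),
              c(0.55, 0.15, 0.20),
              c(0.30, 0.10, 0.25),
              c(0.10, 0.08, 0.14)))

#' Berry color for a latent darkness value
#'
#' Piecewise-linear interpolation between fixed RGB anchors spanning
#' green-yellow (0) to blue-black (1).
#'
#' @param d Darkness values (clipped to `[0, 1]`).
#' @return `length(d) x 3` matrix of RGB on `[0, 1]`.
#' @export
darkness_to_rgb <- function(d) {
  d <- clip01(d)
  an <- .darkness_anchors
  cbind(stats::approx(an$d, an$rgb[, 1], xout = d)$y,
        stats::approx(an$d, an$rgb[, 2], xout = d)$y,
        stats::approx(an$d, an$rgb[, 3], xout = d)$y)
}

# simulate inheritance of one parental chromosome: n x length(pos) matrix of
# 0/1 alleles, Haldane recombination between adjacent positions
sim_chromosome_alleles <- function(n, pos) {
  a <- matrix(0L, n, length(pos))
  a[, 1] <- stats::rbinom(n, 1, 0.5)
  if (length(pos) > 1) {
    rs <- haldane_r(diff(pos))
    for (j in seq_along(rs)) {
      flip <- stats::rbinom(n, 1, rs[j])
      a[, j + 1] <- as.integer(xor(a[, j], flip))
    }
  }
  a
}

#' Simulate a pseudo-testcross population
#'
#' Gametes are simulated per parental map under the Haldane model (no
#' interference), so every marker segregates 1:1 in expectation. The major
#' binary QTL sets noir status with the specified penetrance; minor
#' additive QTL and Gaussian noise feed a latent darkness value, which is
#' mapped to berry RGB and from there to the 11 color traits using the
#' package's colorimetric conventions. OIV scores derive from darkness by
#' fixed thresholds (noir individuals are always scored 6).
#'
#' @param spec A [sim_cross_spec()].
#' @return A [ptcross]; simulation ground truth (noir status, darkness,
#'   QTL allele matrices) is attached as `attr(cross, "truth")`.
#' @export
simulate_cross <- function(spec = sim_cross_spec()) {
  stopifnot(inherits(spec, "sim_cross_spec"))
  with_seed(spec$seed, {
    n <- spec$n_individuals
    maps <- spec$maps
    ids <- sprintf("ind%03d", seq_len(n))
    geno <- matrix(NA_character_, n, nrow(maps),
                   dimnames = list(ids, maps$marker))
    qtl_alleles <- vector("list", length(spec$qtl))
    chrs <- unique(maps[, c("parent", "chr")])
    for (i in seq_len(nrow(chrs))) {
      sel <- maps$parent == chrs$parent[i] & maps$chr == chrs$chr[i]
      mpos <- maps$pos[sel]
      qidx <- which(vapply(spec$qtl, function(q) {
        q$parent == chrs$parent[i] && q$chr == chrs$chr[i]
      }, TRUE))
      qpos <- vapply(spec$qtl[qidx], `[[`, numeric(1), "pos")
      allpos <- sort(unique(c(mpos, qpos)))
      alleles <- sim_chromosome_alleles(n, allpos)
      geno[, maps$marker[sel]] <-
        c("A", "B")[alleles[, match(mpos, allpos), drop = FALSE] + 1L]
      for (k in seq_along(qidx)) {
        qtl_alleles[[qidx[k]]] <- alleles[, match(qpos[k], allpos)]
      }
    }
    # phenotypes
    types <- vapply(spec$qtl, `[[`, "", "type")
    major <- which(types == "binary-major")
    if (length(major) != 1L) {
      stop("exactly one binary-major QTL is required", call. = FALSE)
    }
    b_major <- qtl_alleles[[major]]
    noir <- stats::rbinom(n, 1, ifelse(b_major == 1L, spec$penetrance,
                                       1 - spec$penetrance))
    d <- 0.25 + spec$qtl[[major]]$effect * noir
    for (k in which(types == "additive-minor")) {
      d <- d + spec$qtl[[k]]$effect * (qtl_alleles[[k]] - 0.5)
    }
    d <- d + stats::rnorm(n, 0, spec$residual_sd)
    d <- pmin(pmax(d, 0.02), 0.98)
    rgb01 <- darkness_to_rgb(d)
    traits <- do.call(rbind, lapply(seq_len(n), function(i) {
      color_traits_from_rgb01(rgb01[i, ])
    }))
    oiv_nonnoir <- cut(d, breaks = c(-Inf, 0.18, 0.32, 0.45, 0.6, Inf),
                       labels = FALSE)
    oiv <- ifelse(noir == 1L, 6L, oiv_nonnoir)
    pheno <- cbind(data.frame(id = ids), traits,
                   data.frame(OIV = as.integer(oiv), noir = as.integer(noir)))
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(length(geno)) < spec$missing_rate,
                     nrow(geno), ncol(geno))
      geno[mask] <- NA_character_
    }
    cross <- ptcross(maps, geno, pheno)
    attr(cross, "truth") <- list(spec = spec, noir = noir, darkness = d,
                                 qtl_alleles = qtl_alleles)
    cross
  })
}
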