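# Genotype probabilities along the map.
#
# A two-state hidden Markov chain per chromosome and parental map: hidden
# state = inherited parental allele (A/B), transitions follow the Haldane
# map function (no interference), emissions allow a symmetric genotyping
# error rate. Posterior probabilities are computed at every marker and at
# pseudomarkers on a regular cM grid by forward-backward.

#' Haldane map function
#'
#' Recombination fraction for a map distance in centimorgans:
#' `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM Distance in cM (vectorized).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Inverse Haldane map function
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return Distance in cM.
#' @export
haldane_d <- function(r) -50 * log(1 - 2 * r)

# grid of scan positions for one chromosome: all markers plus pseudomarkers
# every `step` cM between first and last marker
scan_grid <- function(marker_pos, marker_names, chr, step) {
  lo <- marker_pos[1]; hi <- marker_pos[length(marker_pos)]
  pseudo <- if (step > 0 && hi > lo) seq(lo, hi, by = step) else numeric(0)
  pseudo <- setdiff(round(pseudo, 9), round(marker_pos, 9))
  pos <- c(marker_pos, pseudo)
  name <- c(marker_names, sprintf("c%s.loc%g", chr, pseudo))
  is_marker <- c(rep(TRUE, length(marker_pos)), rep(FALSE, length(pseudo)))
  ord <- order(pos, !is_marker)
  data.frame(pos = pos[ord], name = name[ord], is_marker = is_marker[ord],
             stringsAsFactors = FALSE)
}

#' Genotype probabilities at markers and pseudomarkers
#'
#' @param cross A [ptcross].
#' @param step Pseudomarker spacing in cM (> 0).
#' @param error_prob Symmetric genotyping error rate, in `[0, 0.5)`.
#' @return An object of class `genoprob`: a list of per-chromosome entries
#'   (`parent`, `chr`, `pos`, `name`, `is_marker`, and `probB`, an
#'   individuals x positions matrix of P(allele B)).
#' @export
calc_genoprob <- function(cross, step = 1, error_prob = 1e-4) {
  stopifnot(inherits(cross, "ptcross"))
  if (step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (error_prob < 0 || error_prob >= 0.5) {
    stop("`error_prob` must be in [0, 0.5)", call. = FALSE)
  }
  code <- matrix(match(cross$geno, c("A", "B")), nrow(cross$geno),
                 dimnames = dimnames(cross$geno))
  chrs <- unique(cross$map[, c("parent", "chr")])
  entries <- vector("list", nrow(chrs))
  for (i in seq_len(nrow(chrs))) {
    sel <- cross$map$parent == chrs$parent[i] & cross$map$chr == chrs$chr[i]
    mp <- cross$map$pos[sel]
    mn <- cross$map$marker[sel]
    grid <- scan_grid(mp, mn, chrs$chr[i], step)
    obs <- code[, mn, drop = FALSE]
    # align emission lookup by grid name: pseudomarkers have no column
    obs_full <- matrix(NA_integer_, nrow(obs), nrow(grid),
                       dimnames = list(rownames(obs), grid$name))
    obs_full[, mn] <- obs
    probB <- chr_genoprob_grid(obs_full, grid, error_prob)
    entries[[i]] <- list(parent = chrs$parent[i], chr = chrs$chr[i],
                         pos = grid$pos, name = grid$name,
                         is_marker = grid$is_marker, probB = probB)
  }
  structure(list(chromosomes = entries, ids = rownames(cross$geno),
                 step = step, error_prob = error_prob),
            class = "genoprob")
}

# forward-backward where obs is already expanded to the grid (NA at
# pseudomarkers); obs: n x G
chr_genoprob_grid <- function(obs, grid, error_prob) {
  n <- nrow(obs)
  G <- nrow(grid)
  emis <- function(g) {
    E <- matrix(1, n, 2L)
    o <- obs[, g]
    has <- !is.na(o)
    if (any(has)) {
      E[has, 1] <- ifelse(o[has] == 1L, 1 - error_prob, error_prob)
      E[has, 2] <- ifelse(o[has] == 2L, 1 - error_prob, error_prob)
    }
    E
  }
  r_step <- haldane_r(diff(grid$pos))
  fwd <- vector("list", G)
  a <- matrix(0.5, n, 2L) * emis(1L)
  a <- a / rowSums(a)
  fwd[[1L]] <- a
  for (g in seq_len(G - 1L)) {
    r <- r_step[g]
    a2 <- cbind(a[, 1] * (1 - r) + a[, 2] * r,
                a[, 1] * r + a[, 2] * (1 - r)) * emis(g + 1L)
    a <- a2 / rowSums(a2)
    fwd[[g + 1L]] <- a
  }
  probB <- matrix(NA_real_, n, G)
  b <- matrix(1, n, 2L)
  for (g in rev(seq_len(G))) {
    post <- fwd[[g]] * b
    probB[, g] <- post[, 2] / rowSums(post)
    if (g > 1L) {
      r <- r_step[g - 1L]
      x <- emis(g) * b
      b <- cbind(x[, 1] * (1 - r) + x[, 2] * r,
                 x[, 1] * r + x[, 2] * (1 - r))
      b <- b / rowSums(b)
    }
  }
  colnames(probB) <- grid$name
  rownames(probB) <- rownames(obs)
  probB
}

#' @export
print.genoprob <- function(x, ...) {
  np <- sum(vapply(x$chromosomes, function(e) length(e$pos), 1L))
  cat(sprintf("<genoprob> %d individuals, %d chromosomes, %d scan positions (step %g cM, error %g)\n",
              length(x$ids), length(x$chromosomes), np, x$step, x$error_prob))
  invisible(x)
}
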