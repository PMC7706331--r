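# Permutation thresholds, support intervals and QTL summaries.

#' Permutation significance thresholds for a genome scan
#'
#' Phenotypes are permuted against the genotypes `n_perm` times and the
#' scan is re-run on each permutation. Genome scope: the `1 - alpha`
#' quantile of the genome-wide maximum LOD. Chromosome scope: the per-
#' chromosome `1 - alpha` quantile of that chromosome's maximum. Identical
#' seeds give identical permutations, so chromosome-wide thresholds never
#' exceed the genome-wide threshold computed with the same seed.
#'
#' @param cross A [ptcross].
#' @param trait Trait column name in `cross$pheno`, or a numeric vector
#'   aligned with the individuals.
#' @param method Scan method: `"np"`, `"sim"` or `"binary"`.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Significance level in (0, 1).
#' @param scope `"genome"` or `"chromosome"`.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param step,error_prob Passed to [calc_genoprob()] when `genoprob` is not
#'   supplied.
#' @param genoprob Optional precomputed [calc_genoprob()] result.
#' @return An object of class `lod_threshold`: `scope`, `alpha`, `n_perm`,
#'   and `value` (single number for genome scope, or a data frame
#'   `parent, chr, threshold`). The permutation maxima are kept in
#'   `$perm_max` for calibration checks.
#' @export
permutation_threshold <- function(cross, trait, method = c("np", "sim", "binary"),
                                  n_perm = 1000, alpha = 0.05,
                                  scope = c("genome", "chromosome"),
                                  seed, step = 1, error_prob = 1e-4,
                                  genoprob = NULL) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  gp <- genoprob %||% calc_genoprob(cross, step = step, error_prob = error_prob)
  y <- resolve_trait(trait, gp, cross)
  keep <- is.finite(y)
  yv <- y[keep]
  n <- length(yv)
  Pl <- gp_matrices(gp, keep)
  perm_chr_max <- with_seed(seed, {
    if (method %in% c("sim", "np")) {
      base <- if (method == "np") rank(yv) else yv
      Y <- vapply(seq_len(n_perm), function(i) base[sample.int(n)],
                  numeric(n))
      fun <- if (method == "np") np_lod_matrix else hk_lod_matrix
      do.call(rbind, lapply(Pl, function(P) {
        apply(fun(P, Y), 2L, max)                    # chromosomes x perms
      }))
    } else {
      sapply(seq_len(n_perm), function(i) {
        yp <- yv[sample.int(n)]
        vapply(Pl, function(P) max(binary_lod_profile(P, yp)$lod), numeric(1))
      })
    }
  })
  perm_chr_max <- matrix(perm_chr_max, nrow = length(Pl))
  genome_max <- apply(perm_chr_max, 2L, max)
  chrs <- data.frame(
    parent = vapply(gp$chromosomes, `[[`, "", "parent"),
    chr = vapply(gp$chromosomes, `[[`, "", "chr"))
  value <- if (scope == "genome") {
    unname(stats::quantile(genome_max, 1 - alpha))
  } else {
    cbind(chrs, threshold = apply(perm_chr_max, 1L, stats::quantile,
                                  probs = 1 - alpha))
  }
  structure(list(scope = scope, alpha = alpha, n_perm = n_perm,
                 method = method, value = value,
                 perm_max = if (scope == "genome") genome_max else perm_chr_max),
            class = "lod_threshold")
}

#' @export
print.lod_threshold <- function(x, ...) {
  cat(sprintf("<lod_threshold> %s-wide, alpha = %g, %d permutations (%s scan)\n",
              x$scope, x$alpha, x$n_perm, x$method))
  if (x$scope == "genome") cat("  threshold:", format(x$value, digits = 4), "\n")
  else print(x$value)
  invisible(x)
}

#' 1.5-LOD support interval
#'
#' The smallest contiguous run of scan positions containing the peak where
#' `LOD >= max - drop`, expanded one scan position outward on each side and
#' clamped at the chromosome ends.
#'
#' @param result A `scan_result`.
#' @param parent Parental map of the chromosome.
#' @param chr Chromosome name.
#' @param drop LOD drop defining the interval (default 1.5).
#' @return Numeric `c(lo, hi)` in cM.
#' @export
lod_support_interval <- function(result, parent, chr, drop = 1.5) {
  sel <- result$parent == parent & result$chr == as.character(chr)
  if (!any(sel)) {
    stop(sprintf("no scan positions on %s chromosome %s", parent, chr),
         call. = FALSE)
  }
  pos <- result$pos[sel]
  lod <- result$lod[sel]
  ord <- order(pos)
  pos <- pos[ord]; lod <- lod[ord]
  peak <- which.max(lod)
  thr <- lod[peak] - drop
  lo <- peak
  while (lo > 1L && lod[lo - 1L] >= thr) lo <- lo - 1L
  hi <- peak
  while (hi < length(lod) && lod[hi + 1L] >= thr) hi <- hi + 1L
  lo <- max(lo - 1L, 1L)
  hi <- min(hi + 1L, length(lod))
  c(lo = pos[lo], hi = pos[hi])
}

#' Percent variance explained implied by a LOD score
#'
#' The single-QTL relation `PVE = 100 (1 - 10^(-2 LOD / n))`.
#'
#' @param lod LOD score(s), >= 0.
#' @param n Number of individuals used in the scan.
#' @return Percent variance explained.
#' @export
pve_from_lod <- function(lod, n) {
  if (any(lod < 0)) stop("`lod` must be >= 0", call. = FALSE)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  100 * (1 - 10^(-2 * lod / n))
}

#' Summarize significant QTL from a scan
#'
#' For every chromosome whose maximum LOD exceeds its threshold, reports
#' the peak position, the nearest named marker (ties resolved toward the
#' lower cM position), the 1.5-LOD support interval and the percent
#' variance explained.
#'
#' @param result A `scan_result`.
#' @param thresholds A [permutation_threshold()] result (either scope), or a
#'   single numeric genome-wide threshold.
#' @param drop LOD drop for the support interval.
#' @return Data frame with one row per significant QTL: `trait`, `method`,
#'   `parent`, `chr`, `max_lod`, `marker`, `pos`, `interval_lo`,
#'   `interval_hi`, `pve`.
#' @export
summarize_qtl <- function(result, thresholds, drop = 1.5) {
  n_used <- attr(result, "n_used")
  thr_for <- function(parent, chr) {
    if (is.numeric(thresholds)) return(thresholds)
    stopifnot(inherits(thresholds, "lod_threshold"))
    if (thresholds$scope == "genome") return(thresholds$value)
    v <- thresholds$value
    row <- v$parent == parent & v$chr == chr
    if (!any(row)) return(Inf)
    v$threshold[row]
  }
  chrs <- unique(result[, c("parent", "chr")])
  calls <- list()
  for (i in seq_len(nrow(chrs))) {
    pa <- chrs$parent[i]; ch <- chrs$chr[i]
    sel <- result$parent == pa & result$chr == ch
    sub <- result[sel, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    peak <- which.max(sub$lod)
    if (sub$lod[peak] <= thr_for(pa, ch)) next
    mk <- sub[!is.na(sub$marker), , drop = FALSE]
    dist <- abs(mk$pos - sub$pos[peak])
    nearest <- mk$marker[order(dist, mk$pos)][1]
    ci <- lod_support_interval(result, pa, ch, drop = drop)
    calls[[length(calls) + 1L]] <- data.frame(
      trait = attr(result, "trait"), method = attr(result, "method"),
      parent = pa, chr = ch, max_lod = sub$lod[peak], marker = nearest,
      pos = sub$pos[peak], interval_lo = ci[["lo"]], interval_hi = ci[["hi"]],
      pve = pve_from_lod(sub$lod[peak], n_used),
      stringsAsFactors = FALSE)
  }
  if (!length(calls)) {
    return(data.frame(trait = character(), method = character(),
                      parent = character(), chr = character(),
                      max_lod = numeric(), marker = character(),
                      pos = numeric(), interval_lo = numeric(),
                      interval_hi = numeric(), pve = numeric()))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
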