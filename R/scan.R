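# Single-QTL genome scans on a pseudo-testcross.
#
# Three engines, all operating on the genotype probabilities P(B) at each
# scan position:
#   scan_sim    Haley-Knott regression of the trait on P(B);
#               LOD = (n/2) log10(RSS0 / RSS1)
#   scan_np     rank-based scan: the two-group Kruskal-Wallis statistic
#               extended to incomplete genotype information by using P(B)
#               as the group weight; LOD = statistic / (2 ln 10)
#   scan_binary logistic regression of a 0/1 trait on P(B);
#               LOD = (LL1 - LL0) / ln 10
# The cores are vectorized across positions (and, for the regression-based
# scans, across permuted phenotypes) so permutation thresholds stay cheap.

# Haley-Knott LOD for every position (columns of P) x phenotype column of Y.
# P: n x m probabilities, Y: n x k phenotypes (no missing values).
hk_lod_matrix <- function(P, Y) {
  n <- nrow(P)
  Xc <- sweep(P, 2L, colMeans(P))
  Sxx <- colSums(Xc^2)
  Yc <- sweep(Y, 2L, colMeans(Y))
  Syy <- colSums(Yc^2)
  Sxy <- crossprod(Xc, Yc)                       # m x k
  RSS1 <- sweep(-(Sxy^2 / pmax(Sxx, 1e-300)), 2L, Syy, "+")
  mono <- Sxx < 1e-12
  if (any(mono)) {
    RSS1[mono, ] <- matrix(Syy, sum(mono), ncol(Y), byrow = TRUE)
  }
  floorv <- matrix(Syy * 1e-12, nrow(RSS1), ncol(RSS1), byrow = TRUE)
  capped <- RSS1 < floorv
  RSS1 <- pmax(RSS1, floorv)
  lod <- (n / 2) * log10(sweep(1 / RSS1, 2L, Syy, "*"))
  lod <- pmax(lod, 0)
  attr(lod, "capped") <- capped
  lod
}

# Rank-scan LOD for positions x rank-vector columns. Rk holds (possibly
# permuted) mid-ranks of the trait. At a fully informative position the
# statistic is the classical two-group Kruskal-Wallis H (tie correction
# included via the observed rank variance).
np_lod_matrix <- function(P, Rk) {
  n <- nrow(P)
  Xc <- sweep(P, 2L, colMeans(P))
  Sxx <- colSums(Xc^2)
  Rc <- sweep(Rk, 2L, colMeans(Rk))
  SSR <- colSums(Rc^2)
  Tm <- crossprod(Xc, Rc)                        # m x k
  Z2 <- Tm^2 / pmax(Sxx, 1e-300)
  Z2 <- sweep(Z2, 2L, pmax(SSR, 1e-300) / (n - 1), "/")
  Z2[Sxx < 1e-12, ] <- 0
  Z2 / (2 * log(10))
}

# Logistic-regression LOD profile for one 0/1 phenotype across all columns
# of P, by Newton iterations vectorized over positions.
binary_lod_profile <- function(P, y, max_iter = 50L, tol = 1e-10) {
  n <- nrow(P); m <- ncol(P)
  ybar <- mean(y)
  ll0 <- sum(y * log(ybar) + (1 - y) * log(1 - ybar))
  b0 <- rep(stats::qlogis(ybar), m)
  b1 <- rep(0, m)
  degen <- apply(P, 2L, function(p) max(p) - min(p) < 1e-12)
  for (it in seq_len(max_iter)) {
    Eta <- matrix(b0, n, m, byrow = TRUE) + P * matrix(b1, n, m, byrow = TRUE)
    Mu <- stats::plogis(Eta)
    Mu <- pmin(pmax(Mu, 1e-12), 1 - 1e-12)
    W <- Mu * (1 - Mu)
    res <- y - Mu
    g0 <- colSums(res)
    g1 <- colSums(P * res)
    sw <- colSums(W); swx <- colSums(W * P); swxx <- colSums(W * P * P)
    det <- sw * swxx - swx^2
    bad <- degen | det < 1e-12
    det[bad] <- 1
    d0 <- (swxx * g0 - swx * g1) / det
    d1 <- (sw * g1 - swx * g0) / det
    d0[bad] <- g0[bad] / pmax(sw[bad], 1e-12)    # intercept-only update
    d1[bad] <- 0
    # damp huge steps (quasi-separation)
    sc <- pmax(1, pmax(abs(d0), abs(d1)) / 5)
    b0 <- b0 + d0 / sc
    b1 <- b1 + d1 / sc
    if (max(abs(d0), abs(d1)) < tol) break
  }
  Eta <- matrix(b0, n, m, byrow = TRUE) + P * matrix(b1, n, m, byrow = TRUE)
  Mu <- pmin(pmax(stats::plogis(Eta), 1e-12), 1 - 1e-12)
  ll1 <- colSums(y * log(Mu) + (1 - y) * log(1 - Mu))
  sep <- apply(Mu, 2L, function(mu) any(mu > 1 - 1e-6) && any(mu < 1e-6)) &
    abs(b1) > 10
  lod <- pmax((ll1 - ll0) / log(10), 0)
  list(lod = lod, separation = sep)
}

# assemble per-chromosome prob matrices restricted to phenotyped individuals
gp_matrices <- function(gp, keep) {
  lapply(gp$chromosomes, function(e) e$probB[keep, , drop = FALSE])
}

scan_result_frame <- function(gp, lod_list, method, trait, n_used,
                              capped = NULL, separation = NULL) {
  rows <- do.call(rbind, lapply(seq_along(gp$chromosomes), function(i) {
    e <- gp$chromosomes[[i]]
    data.frame(parent = e$parent, chr = e$chr, pos = e$pos,
               marker = ifelse(e$is_marker, e$name, NA_character_),
               lod = lod_list[[i]], stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  structure(rows, class = c("scan_result", "data.frame"),
            method = method, trait = trait, n_used = n_used,
            capped = capped, separation = separation)
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> method %s, trait '%s', n = %d, %d positions; max LOD %.3f\n",
              attr(x, "method"), attr(x, "trait"), attr(x, "n_used"),
              nrow(x), max(x$lod)))
  invisible(as.data.frame(x))
}

# resolve a trait argument (column name or numeric vector) to a numeric
# vector aligned with gp$ids
resolve_trait <- function(y, gp, cross = NULL) {
  if (is.character(y) && length(y) == 1L) {
    if (is.null(cross)) stop("pass the cross to look up a trait by name", call. = FALSE)
    if (!y %in% names(cross$pheno)) {
      stop(sprintf("trait '%s' not in phenotype table", y), call. = FALSE)
    }
    out <- cross$pheno[[y]][match(gp$ids, cross$pheno$id)]
    names(out) <- gp$ids
    return(out)
  }
  if (length(y) != length(gp$ids)) {
    stop("phenotype length does not match the genotyped individuals", call. = FALSE)
  }
  y
}

#' Simple interval mapping (Haley-Knott regression)
#'
#' At each scan position the trait is regressed on P(B);
#' `LOD = (n/2) log10(RSS0/RSS1)` with RSS0 from the intercept-only model.
#' Individuals with a missing trait value are dropped. A perfect fit
#' (RSS1 = 0) is reported at a finite cap and flagged in
#' `attr(result, "capped")`.
#'
#' @param gp A [calc_genoprob()] result.
#' @param y Numeric trait values aligned with the genotyped individuals
#'   (missing allowed).
#' @param trait Trait name for reporting.
#' @return A `scan_result` data frame: `parent`, `chr`, `pos`, `marker`,
#'   `lod`.
#' @export
scan_sim <- function(gp, y, trait = deparse(substitute(y))) {
  stopifnot(inherits(gp, "genoprob"))
  keep <- is.finite(y)
  n <- sum(keep)
  if (n < 10) stop("need >= 10 non-missing phenotypes", call. = FALSE)
  yv <- y[keep]
  if (stats::sd(yv) == 0) stop("degenerate trait: constant values", call. = FALSE)
  Y <- matrix(yv, ncol = 1L)
  lods <- lapply(gp_matrices(gp, keep), function(P) hk_lod_matrix(P, Y))
  capped <- any(vapply(lods, function(l) any(attr(l, "capped")), TRUE))
  scan_result_frame(gp, lapply(lods, as.numeric), "sim", trait, n,
                    capped = capped)
}

#' Nonparametric (rank-based) interval mapping
#'
#' The trait is converted to mid-ranks; at each position the two-group
#' Kruskal-Wallis statistic, extended to partially informative positions by
#' weighting individuals with P(B), is reported as
#' `LOD = statistic / (2 ln 10)`. Invariant under monotone transformations
#' of the trait; robust to nonnormal distributions.
#'
#' @inheritParams scan_sim
#' @return A `scan_result` data frame.
#' @export
scan_np <- function(gp, y, trait = deparse(substitute(y))) {
  stopifnot(inherits(gp, "genoprob"))
  keep <- is.finite(y)
  n <- sum(keep)
  if (n < 10) stop("need >= 10 non-missing phenotypes", call. = FALSE)
  yv <- y[keep]
  if (stats::sd(yv) == 0) stop("degenerate trait: constant values", call. = FALSE)
  Rk <- matrix(rank(yv), ncol = 1L)
  lods <- lapply(gp_matrices(gp, keep), function(P) np_lod_matrix(P, Rk))
  scan_result_frame(gp, lapply(lods, as.numeric), "np", trait, n)
}

#' Binary-trait interval mapping
#'
#' Logistic regression of a 0/1 trait on P(B) at each position, fitted by
#' Newton-Raphson; `LOD = (LL1 - LL0) / ln 10` against the intercept-only
#' model. Complete separation yields a finite LOD bounded by `-LL0/ln 10`
#' and is flagged in `attr(result, "separation")`.
#'
#' @inheritParams scan_sim
#' @return A `scan_result` data frame.
#' @export
scan_binary <- function(gp, y, trait = deparse(substitute(y))) {
  stopifnot(inherits(gp, "genoprob"))
  keep <- is.finite(y)
  n <- sum(keep)
  if (n < 10) stop("need >= 10 individuals", call. = FALSE)
  yv <- y[keep]
  if (!all(yv %in% c(0, 1))) stop("binary trait must be coded 0/1", call. = FALSE)
  if (length(unique(yv)) < 2) {
    stop("degenerate trait: only one class present", call. = FALSE)
  }
  fits <- lapply(gp_matrices(gp, keep), function(P) binary_lod_profile(P, yv))
  scan_result_frame(gp, lapply(fits, `[[`, "lod"), "binary", trait, n,
                    separation = any(unlist(lapply(fits, `[[`, "separation"))))
}

#' Run a scan by method name
#'
#' @param gp A [calc_genoprob()] result.
#' @param y Trait values.
#' @param method `"sim"`, `"np"` or `"binary"`.
#' @param trait Trait name for reporting.
#' @return A `scan_result`.
#' @export
scan_trait <- function(gp, y, method = c("np", "sim", "binary"),
                       trait = deparse(substitute(y))) {
  method <- match.arg(method)
  switch(method,
         sim = scan_sim(gp, y, trait = trait),
         np = scan_np(gp, y, trait = trait),
         binary = scan_binary(gp, y, trait = trait))
}
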