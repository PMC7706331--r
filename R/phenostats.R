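# Population-level statistics on the color phenotypes.

#' Binarize an OIV 225 color score
#'
#' OIV descriptor 225 scores grape skin color 1 (green-yellow) through 6
#' (blue-black). Noir means blue-black: score 6 maps to 1, scores 1-5 to 0.
#'
#' @param score Integer vector of OIV scores in 1-6.
#' @return Integer vector of 0/1 noir indicators.
#' @export
oiv_to_binary <- function(score) {
  if (any(!is.finite(score)) || any(score != round(score)) ||
      any(score < 1) || any(score > 6)) {
    stop("OIV scores must be integers in 1..6", call. = FALSE)
  }
  as.integer(score == 6)
}

#' Chi-square test of 1:1 segregation
#'
#' Pearson goodness-of-fit test of observed noir/nonnoir counts against
#' equal expected counts, 1 degree of freedom, no continuity correction.
#'
#' @param n_noir,n_nonnoir Observed class counts.
#' @return List with `statistic`, `p_value`, `n_noir`, `n_nonnoir`.
#' @export
chi_square_1to1 <- function(n_noir, n_nonnoir) {
  if (n_noir < 0 || n_nonnoir < 0) stop("counts must be >= 0", call. = FALSE)
  if (n_noir + n_nonnoir < 1) stop("need at least one observation", call. = FALSE)
  ct <- suppressWarnings(
    stats::chisq.test(c(n_noir, n_nonnoir), p = c(0.5, 0.5))
  )
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       n_noir = n_noir, n_nonnoir = n_nonnoir)
}

#' Shapiro-Wilk normality screen
#'
#' Runs a Shapiro-Wilk test per trait and flags traits with `p < 0.001`
#' as nonnormal (the screening cutoff used when choosing rank-based QTL
#' scans over parametric ones).
#'
#' @param values Numeric vector, or a data frame whose numeric columns are
#'   each tested.
#' @return Data frame with columns `trait`, `W`, `p`, `nonnormal`.
#' @export
normality_report <- function(values) {
  if (is.data.frame(values)) {
    cols <- names(values)[vapply(values, is.numeric, TRUE)]
    out <- do.call(rbind, lapply(cols, function(cn) {
      r <- normality_report(values[[cn]])
      r$trait <- cn
      r
    }))
    rownames(out) <- NULL
    return(out)
  }
  x <- values[is.finite(values)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk needs 3 to 5000 finite values", call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("degenerate input: trait is constant", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  data.frame(trait = NA_character_, W = unname(sw$statistic),
             p = sw$p.value, nonnormal = sw$p.value < 0.001)
}

#' Between-year Pearson correlations by color subset
#'
#' Joins two phenotype tables on genotype id and reports Pearson r per
#' trait. Subsets: `"noir"` keeps genotypes scored noir in both years,
#' `"nonnoir"` those nonnoir in both years; genotypes that switch class are
#' excluded from the subsets but kept in `"all"`. Entries with `p >= 0.05`
#' are flagged not significant.
#'
#' @param tableA,tableB Phenotype tables with an `id` column, trait columns
#'   and a `noir` indicator column.
#' @param subset One of `"all"`, `"noir"`, `"nonnoir"`.
#' @param traits Trait columns to correlate; defaults to the shared
#'   numeric trait columns.
#' @return Data frame with `trait`, `r`, `p`, `n`, `significant`.
#' @export
correlations_between_years <- function(tableA, tableB,
                                       subset = c("all", "noir", "nonnoir"),
                                       traits = NULL) {
  subset <- match.arg(subset)
  stopifnot("id" %in% names(tableA), "id" %in% names(tableB))
  m <- merge(tableA, tableB, by = "id", suffixes = c(".A", ".B"))
  if (subset != "all") {
    if (!all(c("noir.A", "noir.B") %in% names(m))) {
      stop("subsetting needs a `noir` column in both tables", call. = FALSE)
    }
    want <- as.integer(subset == "noir")
    m <- m[m$noir.A == want & m$noir.B == want, , drop = FALSE]
  }
  if (is.null(traits)) {
    shared <- intersect(names(tableA), names(tableB))
    traits <- setdiff(shared[vapply(tableA[shared], is.numeric, TRUE)],
                      c("id", "noir", "n_berry_pixels"))
  }
  if (nrow(m) < 3) {
    stop(sprintf("fewer than 3 shared genotypes in subset '%s'", subset),
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(traits, function(tr) {
    a <- m[[paste0(tr, ".A")]]; b <- m[[paste0(tr, ".B")]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(data.frame(trait = tr, r = NA_real_, p = NA_real_,
                        n = sum(ok), significant = NA))
    }
    ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
    data.frame(trait = tr, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), significant = ct$p.value < 0.05)
  }))
  rownames(out) <- NULL
  out
}

#' PCA of color traits
#'
#' Principal components of the selected trait columns after standardizing
#' each to zero mean and unit variance (i.e. an eigendecomposition of the
#' correlation matrix) -- the traits mix 0-255, degree and unit scales, so
#' the covariance matrix would be dominated by the large-scale channels.
#' Component signs are fixed so each component's largest-magnitude loading
#' is positive.
#'
#' @param table Phenotype table (data frame).
#' @param traits Character vector of >= 2 trait columns.
#' @return List with `scores`, `loadings`, `variance_fraction`.
#' @export
pca_traits <- function(table, traits) {
  if (length(traits) < 2) stop("need at least 2 traits", call. = FALSE)
  missing <- setdiff(traits, names(table))
  if (length(missing)) {
    stop(sprintf("trait column(s) not found: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(table[, traits])
  if (nrow(x) < 3) stop("need at least 3 rows", call. = FALSE)
  if (anyNA(x)) stop("missing values among selected traits", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("degenerate (constant) trait column: %s",
                 paste(traits[sds == 0], collapse = ", ")), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, variance_fraction = vf)
}
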