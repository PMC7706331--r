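# Pseudo-testcross container and delimited I/O.
#
# An F1 of two heterozygous parents: markers heterozygous in one parent
# segregate 1:1 in the progeny, giving separate maternal and paternal maps.
# Genotypes take two classes per marker, coded A/B ('-' or NA = missing).

PARENTAL_MAPS <- c("maternal", "paternal")

#' Construct a pseudo-testcross
#'
#' @param map Data frame with columns `marker`, `chr`, `pos` (cM,
#'   nondecreasing within chromosome) and `parent`
#'   (`"maternal"`/`"paternal"`).
#' @param geno Character matrix (individuals x markers) with codes `"A"`,
#'   `"B"`, `NA`; row names are individual ids, column names marker names.
#' @param pheno Data frame with an `id` column matching the genotype rows,
#'   plus trait columns.
#' @return An object of class `ptcross` with a per-marker segregation
#'   summary in `$marker_summary`.
#' @export
ptcross <- function(map, geno, pheno) {
  need <- c("marker", "chr", "pos", "parent")
  if (!all(need %in% names(map))) {
    stop("map needs columns marker, chr, pos, parent", call. = FALSE)
  }
  if (anyDuplicated(map$marker)) stop("marker names must be unique", call. = FALSE)
  if (!all(map$parent %in% PARENTAL_MAPS)) {
    stop("map parent must be 'maternal' or 'paternal'", call. = FALSE)
  }
  map$chr <- as.character(map$chr)
  map <- map[order(match(map$parent, PARENTAL_MAPS), map$chr, map$pos), ]
  for (key in split(seq_len(nrow(map)), paste(map$parent, map$chr))) {
    if (is.unsorted(map$pos[key])) {
      stop("marker positions must be nondecreasing within chromosome",
           call. = FALSE)
    }
  }
  geno <- as.matrix(geno)
  if (!setequal(colnames(geno), map$marker)) {
    stop("genotype columns and map markers differ", call. = FALSE)
  }
  geno <- geno[, map$marker, drop = FALSE]
  if ("id" %in% names(pheno)) pheno$id <- as.character(pheno$id)
  else stop("phenotype table needs an `id` column", call. = FALSE)
  if (is.null(rownames(geno))) {
    stop("genotype matrix needs individual ids as row names", call. = FALSE)
  }
  only_g <- setdiff(rownames(geno), pheno$id)
  only_p <- setdiff(pheno$id, rownames(geno))
  if (length(only_g) || length(only_p)) {
    stop(sprintf(
      "genotype/phenotype id mismatch (%s)",
      paste(c(
        if (length(only_g)) sprintf("no phenotype for: %s",
                                    paste(utils::head(only_g, 5), collapse = ", ")),
        if (length(only_p)) sprintf("no genotype for: %s",
                                    paste(utils::head(only_p, 5), collapse = ", "))
      ), collapse = "; ")), call. = FALSE)
  }
  pheno <- pheno[match(rownames(geno), pheno$id), , drop = FALSE]
  rownames(pheno) <- NULL
  bad <- !(geno %in% c("A", "B") | is.na(geno))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown genotype code '%s' (individual %s, marker %s)",
                 geno[w[1], w[2]], rownames(geno)[w[1]],
                 colnames(geno)[w[2]]), call. = FALSE)
  }
  nA <- colSums(geno == "A", na.rm = TRUE)
  nB <- colSums(geno == "B", na.rm = TRUE)
  seg_p <- vapply(seq_along(nA), function(j) {
    if (nA[j] + nB[j] == 0) return(NA_real_)
    suppressWarnings(stats::chisq.test(c(nA[j], nB[j]),
                                       p = c(0.5, 0.5))$p.value)
  }, numeric(1))
  ms <- data.frame(marker = map$marker, chr = map$chr, pos = map$pos,
                   parent = map$parent, n_A = as.numeric(nA),
                   n_B = as.numeric(nB),
                   n_missing = nrow(geno) - as.numeric(nA) - as.numeric(nB),
                   seg_p = seg_p,
                   monomorphic = nA == 0 | nB == 0)
  structure(list(map = map, geno = geno, pheno = pheno,
                 marker_summary = ms),
            class = "ptcross")
}

#' @export
print.ptcross <- function(x, ...) {
  cat(sprintf(
    "<ptcross> %d individuals, %d markers (%d maternal / %d paternal), %d chromosomes per map\n",
    nrow(x$geno), nrow(x$map), sum(x$map$parent == "maternal"),
    sum(x$map$parent == "paternal"),
    length(unique(x$map$chr[x$map$parent == "maternal"]))))
  cat(sprintf("  phenotypes: %s\n",
              paste(setdiff(names(x$pheno), "id"), collapse = ", ")))
  invisible(x)
}

#' Number of individuals in a cross
#' @param cross A [ptcross].
#' @export
n_individuals <- function(cross) nrow(cross$geno)

#' Read a cross from delimited files
#'
#' `map_file`: columns `marker, chr, pos, parent`. `geno_file`: one row per
#' individual, first column `id`, then one column per marker with codes
#' `A`, `B`, `-` (missing). `pheno_file`: column `id` plus trait columns.
#'
#' @param map_file,geno_file,pheno_file CSV file paths.
#' @return A [ptcross].
#' @export
read_cross <- function(map_file, geno_file, pheno_file) {
  map <- utils::read.csv(map_file, stringsAsFactors = FALSE)
  g <- utils::read.csv(geno_file, stringsAsFactors = FALSE,
                       check.names = FALSE, colClasses = "character")
  pheno <- utils::read.csv(pheno_file, stringsAsFactors = FALSE)
  if (!"id" %in% names(g)) stop("genotype file needs an `id` column", call. = FALSE)
  ids <- g$id
  geno <- as.matrix(g[, setdiff(names(g), "id"), drop = FALSE])
  geno[geno %in% c("-", "")] <- NA
  rownames(geno) <- ids
  ptcross(map, geno, pheno)
}

#' Write a cross to delimited files
#'
#' Inverse of [read_cross()]: writes `map.csv`, `geno.csv`, `pheno.csv`
#' into a directory.
#'
#' @param cross A [ptcross].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cross <- function(cross, dir) {
  stopifnot(inherits(cross, "ptcross"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cross$map, file.path(dir, "map.csv"), row.names = FALSE)
  g <- cross$geno
  g[is.na(g)] <- "-"
  utils::write.csv(cbind(data.frame(id = rownames(g)), as.data.frame(g)),
                   file.path(dir, "geno.csv"), row.names = FALSE)
  utils::write.csv(cross$pheno, file.path(dir, "pheno.csv"),
                   row.names = FALSE)
  invisible(dir)
}
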