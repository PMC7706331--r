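# Fixtures built in code; no binary files.

# uniform H x W image of one color
uniform_image <- function(color, H = 6, W = 6, id = "fix") {
  rgb_image(array(rep(color, each = H * W), dim = c(H, W, 3)), id = id)
}

# a tiny hand-written cross: two chromosomes on the maternal map, one on the
# paternal, complete or partly missing genotypes
tiny_cross <- function() {
  map <- data.frame(
    marker = c("m1", "m2", "m3", "p1"),
    chr = c("1", "1", "1", "1"),
    pos = c(0, 10, 25, 0),
    parent = c("maternal", "maternal", "maternal", "paternal"))
  geno <- matrix(c("A", "A", "B", "A",
                   "A", "B", "B", "B",
                   "B", "B", "A", "A",
                   "A", "B", "A", "B"),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("i", 1:4), map$marker))
  pheno <- data.frame(id = paste0("i", 1:4), y = c(1.2, 3.4, 2.2, 0.4),
                      noir = c(0, 1, 1, 0))
  ptcross(map, geno, pheno)
}

# cross with a single fully informative marker and a chosen phenotype:
# the workhorse for single-marker oracle checks
single_marker_cross <- function(y, geno_class, noir = NULL) {
  n <- length(y)
  ids <- sprintf("s%03d", seq_len(n))
  map <- data.frame(marker = "mk1", chr = "1", pos = 0, parent = "maternal")
  geno <- matrix(c("A", "B")[geno_class + 1L], ncol = 1,
                 dimnames = list(ids, "mk1"))
  pheno <- data.frame(id = ids, y = y)
  if (!is.null(noir)) pheno$noir <- noir
  ptcross(map, geno, pheno)
}

# small quick settings for image-based tests
small_cluster_spec <- function(...) {
  cluster_spec(n_berries = 14, berry_radius = c(8, 1.2),
               image_size = c(110, 110), ...)
}
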