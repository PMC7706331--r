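# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# round half away from zero; base round() rounds half to even
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce a length-3 vector or n x 3 matrix to an n x 3 matrix
as_rgb_matrix <- function(rgb, arg = "rgb") {
  if (is.null(dim(rgb))) {
    if (length(rgb) != 3L) {
      stop(sprintf("`%s` must have 3 values (R, G, B)", arg), call. = FALSE)
    }
    rgb <- matrix(rgb, nrow = 1L)
  }
  rgb <- as.matrix(rgb)
  if (ncol(rgb) != 3L) {
    stop(sprintf("`%s` must have 3 columns (R, G, B)", arg), call. = FALSE)
  }
  storage.mode(rgb) <- "double"
  rgb
}
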