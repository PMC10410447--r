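#' @keywords internal
"_PACKAGE"

# Boltzmann constant, kJ/(mol K)
.kB <- 0.008314462618

#' Run code with a locally seeded RNG
#'
#' Saves and restores the caller's RNG state so that seeded operations inside
#' the package never perturb the user's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Pairwise squared cross-distances between two coordinate sets
#' @param a,b numeric matrices, N x 3 and M x 3.
#' @return N x M matrix of squared Euclidean distances.
#' @keywords internal
#' @noRd
cross_dist2 <- function(a, b) {
  # |a|^2 + |b|^2 - 2 a.b, clipped at 0 against rounding
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

stopifnot_mat3 <- function(x, what = "coordinates") {
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x))
    stop(what, " must be a numeric N x 3 matrix", call. = FALSE)
  if (anyNA(x)) stop(what, " contain missing values", call. = FALSE)
  invisible(x)
}

#' Stable hash of an R configuration object
#'
#' MD5 of the canonical JSON serialization, used to stamp pipeline outputs.
#' @param x an R object (list of scalars/vectors).
#' @return character MD5 digest.
#' @keywords internal
#' @noRd
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}
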