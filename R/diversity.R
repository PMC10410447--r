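# Stratified CDR-H3 conformational-diversity statistics: per-stratum mean
# DTW distance relative to the whole-set baseline, with bootstrap
# significance obtained by drawing random pseudo-strata of matching size.

.as_member_idx <- function(D, members) {
  ids <- rownames(D)
  if (is.character(members)) {
    idx <- match(members, ids)
    if (anyNA(idx)) stop("members absent from the distance matrix: ",
                         paste(members[is.na(idx)], collapse = ", "),
                         call. = FALSE)
    idx
  } else if (is.logical(members)) which(members)
  else as.integer(members)
}

#' Mean intra-set DTW distance
#'
#' Mean of the off-diagonal entries over all unordered pairs of the member
#' set. With all ids as members this is the baseline (whole data set)
#' diversity.
#'
#' @param D symmetric distance matrix (e.g. from [pairwise_dtw()]).
#' @param members ids (character), indices or logical mask; at least 2.
#' @return mean pairwise distance in angstrom.
#' @export
mean_intra_distance <- function(D, members = NULL) {
  if (is.null(members)) members <- seq_len(nrow(D))
  idx <- .as_member_idx(D, members)
  k <- length(idx)
  if (k < 2) stop("need at least 2 members", call. = FALSE)
  sum(D[idx, idx]) / (k * (k - 1))
}

#' Bootstrap null deltas for a stratum size
#'
#' Draws `n_boot` random pseudo-strata of size `m` (without replacement by
#' default) and returns the replicate differences between pseudo-stratum
#' mean and baseline mean. Deterministic given the seed; the draws depend
#' only on the matrix, `m`, `n_boot`, `seed` and `replace`, so they can be
#' reused across strata of equal size (see [bootstrap_p()]).
#'
#' @inheritParams mean_intra_distance
#' @param m stratum size.
#' @param n_boot number of replicates.
#' @param seed integer seed.
#' @param replace sample ids with replacement (default FALSE: a random
#'   pseudo-stratum of equal size).
#' @return numeric vector of length `n_boot`.
#' @export
bootstrap_null_deltas <- function(D, m, n_boot = 10000, seed = 1,
                                  replace = FALSE) {
  n <- nrow(D)
  if (m < 2 || m > n) stop("stratum size out of range", call. = FALSE)
  baseline <- mean_intra_distance(D)
  with_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      idx <- sample.int(n, m, replace = replace)
      sum(D[idx, idx]) / (m * (m - 1)) - baseline
    }, numeric(1))
  })
}

#' Bootstrap p-value for a stratum's diversity shift
#'
#' Tests whether the stratum's mean pairwise DTW distance differs from the
#' overall baseline. The observed statistic is
#' `delta = stratum mean - baseline mean`; each replicate draws as many ids
#' from the whole set as the stratum holds and recomputes the statistic. The
#' two-sided p-value counts replicates with an effect of at least the
#' observed magnitude, with +1 smoothing so p is never exactly 0 at finite
#' `n_boot`:
#' `p = (1 + #{|delta*| >= |delta|}) / (1 + n_boot)`.
#'
#' @inheritParams bootstrap_null_deltas
#' @param members stratum ids/indices (>= 2 members).
#' @param sides `"two"` (magnitude, default), `"greater"` or `"less"`.
#' @param null_deltas optional precomputed replicate deltas from
#'   [bootstrap_null_deltas()] for this matrix and stratum size; passing
#'   them is bit-identical to recomputation with the same seed and saves
#'   time when many equal-sized strata are tested.
#' @return list with `p`, `delta`, `mean`, `baseline`, `n`, `n_boot`, `seed`.
#' @export
bootstrap_p <- function(D, members, n_boot = 10000, seed = 1,
                        sides = c("two", "greater", "less"),
                        replace = FALSE, null_deltas = NULL) {
  sides <- match.arg(sides)
  idx <- .as_member_idx(D, members)
  m <- length(idx)
  baseline <- mean_intra_distance(D)
  obs <- mean_intra_distance(D, idx) - baseline
  if (is.null(null_deltas))
    null_deltas <- bootstrap_null_deltas(D, m, n_boot, seed, replace)
  hits <- switch(sides,
                 two = sum(abs(null_deltas) >= abs(obs)),
                 greater = sum(null_deltas >= obs),
                 less = sum(null_deltas <= obs))
  list(p = (1 + hits) / (1 + length(null_deltas)), delta = obs,
       mean = obs + baseline, baseline = baseline, n = m,
       n_boot = length(null_deltas), seed = seed)
}

#' Stratified diversity report
#'
#' One row per stratum with at least 2 members: the stratum's mean pairwise
#' DTW distance, its percent change relative to the whole-set baseline, and
#' the bootstrap p-value. Strata with fewer than 2 members are skipped with
#' a warning. Null replicate draws are cached per stratum size, so
#' equal-sized strata share one set of draws (identical to calling
#' [bootstrap_p()] per stratum with the same seed).
#'
#' @inheritParams bootstrap_p
#' @param stratification data.frame with columns `id` and `stratum`, or a
#'   named character vector (names = ids). Ids missing from the matrix are
#'   an error; ids of the matrix missing from the stratification simply
#'   stay unstratified but still contribute to the baseline.
#' @param alpha significance level for the `significant` flag (default 0.05,
#'   the level marked "*" in diversity figures).
#' @return data.frame with `stratum`, `n`, `mean_dtw`, `baseline_mean`,
#'   `delta_pct`, `p_value`, `significant`, `n_boot`, `seed`.
#' @export
diversity_report <- function(D, stratification, n_boot = 10000, seed = 1,
                             sides = "two", replace = FALSE, alpha = 0.05) {
  if (is.data.frame(stratification)) {
    ids <- stratification$id
    strata <- as.character(stratification$stratum)
  } else {
    ids <- names(stratification)
    strata <- as.character(stratification)
  }
  keep <- !is.na(strata) & strata != ""
  ids <- ids[keep]; strata <- strata[keep]
  if (length(ids) == 0) stop("empty stratification", call. = FALSE)
  .as_member_idx(D, ids)   # validates membership
  labs <- unique(strata)
  sizes <- vapply(labs, function(s) sum(strata == s), integer(1))
  small <- labs[sizes < 2]
  if (length(small))
    warning("skipping strata with < 2 members: ",
            paste(small, collapse = ", "), call. = FALSE)
  labs <- labs[sizes >= 2]
  null_cache <- list()
  rows <- lapply(labs, function(s) {
    mem <- ids[strata == s]
    key <- as.character(length(mem))
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <<- bootstrap_null_deltas(D, length(mem), n_boot,
                                                  seed, replace)
    bp <- bootstrap_p(D, mem, n_boot, seed, sides = sides, replace = replace,
                      null_deltas = null_cache[[key]])
    data.frame(stratum = s, n = bp$n, mean_dtw = bp$mean,
               baseline_mean = bp$baseline,
               delta_pct = 100 * bp$delta / bp$baseline,
               p_value = bp$p, significant = bp$p < alpha,
               n_boot = bp$n_boot, seed = seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
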