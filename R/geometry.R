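# Geometric kernels: Kabsch superposition, RMSD, minimum inter-loop
# distances, the contact criterion, and inter-loop radial distribution
# functions with per-bin comparison statistics.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` over all proper
#' rotations and translations, via SVD of the covariance matrix with the
#' usual sign correction that suppresses reflections.
#'
#' The returned transform acts on row-vector coordinates:
#' `x_new = x %*% rotation + translation` (see [transform_coords()]).
#'
#' @param mobile,reference numeric N x 3 matrices of matched points (N >= 3).
#' @return list of class `rigid_transform` with `rotation` (3 x 3, det +1),
#'   `translation` (length-3), and `rmsd` of the fit in angstrom.
#' @export
kabsch <- function(mobile, reference) {
  stopifnot_mat3(mobile, "mobile"); stopifnot_mat3(reference, "reference")
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ", call. = FALSE)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  h <- crossprod(a, b)                       # 3 x 3 covariance
  sv <- svd(h)
  if (sum(sv$d > max(sv$d) * 1e-9) < 2)
    stop("degenerate geometry: points are collinear or coincident",
         call. = FALSE)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- cr - as.vector(cm %*% rot)
  fitted <- a %*% rot
  structure(list(rotation = rot, translation = trans,
                 rmsd = sqrt(mean(rowSums((fitted - b)^2)))),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param coords N x 3 matrix.
#' @param tf a `rigid_transform` from [kabsch()].
#' @return transformed N x 3 matrix.
#' @export
transform_coords <- function(coords, tf) {
  stopifnot_mat3(coords)
  sweep(coords %*% tf$rotation, 2, tf$translation, "+")
}

#' Root-mean-square deviation of matched coordinates
#'
#' Plain RMSD over matched point pairs. No superposition is performed:
#' superposing first, when wanted, is the caller's explicit step.
#'
#' @param a,b numeric N x 3 matrices in matched order.
#' @return RMSD in angstrom.
#' @export
rmsd_coords <- function(a, b) {
  stopifnot_mat3(a); stopifnot_mat3(b)
  if (nrow(a) != nrow(b)) stop("point counts differ", call. = FALSE)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Minimum heavy-atom distance between two selections
#'
#' @param a,b [select_loop()] selections or bare N x 3 coordinate matrices;
#'   both must be non-empty.
#' @return minimum Euclidean cross-distance in angstrom.
#' @export
min_heavy_distance <- function(a, b) {
  ca <- if (inherits(a, "loop_selection")) a$coords else a
  cb <- if (inherits(b, "loop_selection")) b$coords else b
  stopifnot_mat3(ca); stopifnot_mat3(cb)
  if (nrow(ca) == 0 || nrow(cb) == 0)
    stop("empty selection in min_heavy_distance", call. = FALSE)
  sqrt(min(cross_dist2(ca, cb)))
}

#' Heavy-atom contact criterion
#'
#' Two loops are in contact when their minimum heavy-atom distance falls in
#' the 0-4.5 angstrom range (closed upper bound).
#'
#' @param d distance(s) in angstrom, non-negative.
#' @return logical vector.
#' @export
in_contact <- function(d) {
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  d <= 4.5
}

#' Inter-loop radial distribution function
#'
#' For each structure (or ensemble frame), all cross heavy-atom distances
#' between the two loops are histogrammed in 0.1-angstrom bins up to 10
#' angstrom. Each bin count is divided by the volume of the spherical shell
#' between the bin edges, (4/3)*pi*(r2^3 - r1^3), and by the number of
#' possible atom pairs n_a * n_b, giving a per-structure density in
#' counts per cubic angstrom per pair. Densities are then averaged over
#' structures (weighted when `weights` is given, e.g. reweighted ensemble
#' frames) with t-based 95% confidence half-widths. No unit-cell
#' normalization is applied, so profiles show comparable trends rather than
#' absolute frequencies.
#'
#' @param items list of [fv_structure()] objects, or list of lists
#'   `list(a = <Nx3>, b = <Mx3>)` of pre-extracted heavy-atom coordinates.
#' @param pair character(2) of region labels, e.g. `c("CDR-H3","CDR-L3")`
#'   (required when `items` are structures).
#' @param weights optional non-negative per-item weights (default equal).
#' @param bin_width,r_max histogram geometry in angstrom.
#' @return object of class `rdf_profile`: list with `bin_edges`,
#'   `density` (items x bins matrix), `mean_density`, `ci95`, `counts`
#'   (raw per-item bin counts), `n_items`, `pair`, `weights`.
#' @export
rdf_profile <- function(items, pair = NULL, weights = NULL,
                        bin_width = 0.1, r_max = 10) {
  if (length(items) < 1) stop("need at least one item", call. = FALSE)
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1L
  shell <- (4 / 3) * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  if (is.null(weights)) weights <- rep(1, length(items))
  if (length(weights) != length(items) || any(weights < 0) ||
      sum(weights) <= 0)
    stop("weights must be non-negative, one per item, not all zero",
         call. = FALSE)

  counts <- matrix(0, length(items), nb)
  dens <- matrix(0, length(items), nb)
  for (i in seq_along(items)) {
    it <- items[[i]]
    if (inherits(it, "fv_structure")) {
      if (is.null(pair) || length(pair) != 2)
        stop("a loop pair must be given for structure items", call. = FALSE)
      ca <- select_loop(it, pair[1], "heavy")$coords
      cb <- select_loop(it, pair[2], "heavy")$coords
    } else {
      ca <- it$a; cb <- it$b
    }
    if (nrow(ca) == 0 || nrow(cb) == 0)
      stop("loop with zero heavy atoms in item ", i, call. = FALSE)
    d <- sqrt(cross_dist2(ca, cb))
    idx <- findInterval(d, edges, left.open = FALSE, rightmost.closed = FALSE)
    idx <- idx[idx >= 1 & idx <= nb]      # bins are [left, right)
    if (length(idx)) counts[i, ] <- tabulate(idx, nbins = nb)
    dens[i, ] <- counts[i, ] / (shell * (nrow(ca) * nrow(cb)))
  }

  w <- weights / sum(weights)
  m <- as.vector(w %*% dens)
  n <- length(items)
  if (n >= 2) {
    n_eff <- 1 / sum(w^2)
    v <- as.vector(w %*% sweep(dens, 2, m)^2) / (1 - sum(w^2))
    ci <- stats::qt(0.975, df = n_eff - 1) * sqrt(v / n_eff)
    ci[!is.finite(ci)] <- 0
  } else ci <- rep(0, nb)

  structure(list(bin_edges = edges, density = dens, mean_density = m,
                 ci95 = ci, counts = counts, n_items = n, pair = pair,
                 weights = weights),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat("<rdf_profile> ", if (!is.null(x$pair)) paste(x$pair, collapse = " vs "),
      ": ", x$n_items, " items, ", length(x$mean_density), " bins, peak ",
      signif(max(x$mean_density), 4), " at ",
      x$bin_edges[which.max(x$mean_density)], " A\n", sep = "")
  invisible(x)
}

#' Per-bin comparison of two RDF profiles
#'
#' Two-sided Welch (unequal-variance) two-sample t-test in every distance
#' bin, treating per-structure densities as independent samples. Bins where
#' both groups have zero variance get p = 1 when the means agree and p = 0
#' otherwise. No multiple-testing correction is applied across bins; the
#' p-values are raw per-bin values.
#'
#' @param a,b `rdf_profile` objects with identical bin edges and >= 2 items.
#' @return data.frame with `bin_left`, `bin_right`, `t`, `p`.
#' @export
rdf_compare <- function(a, b) {
  if (!inherits(a, "rdf_profile") || !inherits(b, "rdf_profile"))
    stop("inputs must be rdf_profile objects", call. = FALSE)
  if (!isTRUE(all.equal(a$bin_edges, b$bin_edges)))
    stop("bin edges differ", call. = FALSE)
  if (a$n_items < 2 || b$n_items < 2)
    stop("need at least 2 items per group", call. = FALSE)
  m1 <- colMeans(a$density); m2 <- colMeans(b$density)
  v1 <- apply(a$density, 2, stats::var); v2 <- apply(b$density, 2, stats::var)
  n1 <- a$n_items; n2 <- b$n_items
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  tstat[zero] <- ifelse(m1[zero] == m2[zero], 0, Inf)
  data.frame(bin_left = a$bin_edges[-length(a$bin_edges)],
             bin_right = a$bin_edges[-1], t = tstat, p = p)
}

#' Minimum-distance records for a set of structures
#'
#' Convenience wrapper computing the minimum heavy-atom distance for every
#' unordered CDR pair over a list of structures.
#'
#' @param structures list of [fv_structure()] objects.
#' @param pairs optional list of character(2) label pairs; default all 15
#'   unordered CDR pairs.
#' @return data.frame `id`, `loop_a`, `loop_b`, `distance`, `contact`.
#' @export
min_distance_table <- function(structures, pairs = NULL) {
  if (is.null(pairs)) {
    labs <- cdr_labels()
    pairs <- utils::combn(labs, 2, simplify = FALSE)
  }
  out <- lapply(structures, function(s) {
    sel <- lapply(cdr_labels(), function(l) select_loop(s, l, "heavy"))
    names(sel) <- cdr_labels()
    d <- vapply(pairs, function(p)
      min_heavy_distance(sel[[p[1]]], sel[[p[2]]]), numeric(1))
    data.frame(id = s$id,
               loop_a = vapply(pairs, `[`, character(1), 1),
               loop_b = vapply(pairs, `[`, character(1), 2),
               distance = d, contact = in_contact(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
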