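# Length-independent CDR-H3 comparison: anchor superposition on IMGT
# 100-104/118-122 followed by dynamic time warping over a backbone
# deviation matrix. At equal loop lengths the measure reduces exactly to
# the conventional backbone RMSD after anchor superposition.

.ANCHOR_N <- c(100:104)
.ANCHOR_C <- c(118:122)

#' Construct an anchored loop
#'
#' A CDR-H3 loop represented by its backbone (N, CA, C, O per residue) plus
#' the ten anchoring framework residues (IMGT 100-104 and 118-122) used for
#' superposition. Anchors must be complete (10 residues x 4 atoms);
#' incomplete anchors make a loop ineligible for comparison.
#'
#' @param loop_bb (4L) x 3 matrix of loop backbone coordinates, residues in
#'   order, atoms in N, CA, C, O order within each residue.
#' @param anchor_bb 40 x 3 matrix of anchor backbone coordinates (positions
#'   100-104 then 118-122, same atom order).
#' @param id optional identifier.
#' @return object of class `anchored_loop` with `loop_bb`, `anchor_bb`,
#'   `length` (residues), `id`.
#' @export
anchored_loop <- function(loop_bb, anchor_bb, id = NULL) {
  stopifnot_mat3(loop_bb, "loop backbone")
  stopifnot_mat3(anchor_bb, "anchor backbone")
  if (nrow(loop_bb) %% 4 != 0 || nrow(loop_bb) < 4)
    stop("loop backbone must hold 4 atoms per residue", call. = FALSE)
  if (nrow(anchor_bb) != 40)
    stop("anchors incomplete: need 10 residues x 4 backbone atoms",
         call. = FALSE)
  structure(list(loop_bb = loop_bb, anchor_bb = anchor_bb,
                 length = nrow(loop_bb) / 4L, id = id),
            class = "anchored_loop")
}

#' Extract the anchored CDR-H3 loop from an Fv structure
#'
#' Pulls the CDR-H3 backbone and the IMGT 100-104/118-122 anchor backbone
#' from the heavy chain. Returns `NULL` when the loop or anchors are not
#' fully resolved (all 4 backbone atoms per residue), i.e. the structure is
#' ineligible for DTW comparison.
#'
#' @param fv an [fv_structure()].
#' @return an [anchored_loop()] or `NULL`.
#' @export
anchored_loop_from_fv <- function(fv) {
  a <- fv$atoms[fv$atoms$chain == "H" & fv$atoms$atom %in% .BACKBONE, ,
                drop = FALSE]
  grab <- function(rows) {
    key <- paste(rows$imgt_number, rows$imgt_insertion)
    res <- unique(key)
    out <- matrix(NA_real_, 4 * length(res), 3)
    for (i in seq_along(res)) {
      ri <- rows[key == res[i], , drop = FALSE]
      if (!all(.BACKBONE %in% ri$atom)) return(NULL)
      ri <- ri[match(.BACKBONE, ri$atom), , drop = FALSE]
      out[(4 * i - 3):(4 * i), ] <- as.matrix(ri[, c("x", "y", "z")])
    }
    out
  }
  loop_rows <- a[assign_region(a$imgt_number, "H") == "CDR-H3", , drop = FALSE]
  if (nrow(loop_rows) == 0) return(NULL)
  key <- imgt_order_key(loop_rows$imgt_number, loop_rows$imgt_insertion)
  loop_rows <- loop_rows[order(key), , drop = FALSE]
  anc_rows <- a[a$imgt_number %in% c(.ANCHOR_N, .ANCHOR_C) &
                  a$imgt_insertion == 0, , drop = FALSE]
  if (length(unique(anc_rows$imgt_number)) != 10) return(NULL)
  anc_rows <- anc_rows[order(anc_rows$imgt_number), , drop = FALSE]
  lb <- grab(loop_rows); ab <- grab(anc_rows)
  if (is.null(lb) || is.null(ab)) return(NULL)
  anchored_loop(lb, ab, id = fv$id)
}

#' @export
print.anchored_loop <- function(x, ...) {
  cat("<anchored_loop> ", if (!is.null(x$id)) x$id, " length ", x$length,
      " residues\n", sep = "")
  invisible(x)
}

#' Superpose one anchored loop onto another
#'
#' Rigid transform fitted on the 40 anchor backbone atoms of `a` onto those
#' of `b` ([kabsch()]), applied to both the loop and anchor coordinates of
#' `a`.
#'
#' @param a,b [anchored_loop()] objects.
#' @return a transformed copy of `a`.
#' @export
anchor_superpose <- function(a, b) {
  tf <- kabsch(a$anchor_bb, b$anchor_bb)
  anchored_loop(transform_coords(a$loop_bb, tf),
                transform_coords(a$anchor_bb, tf), id = a$id)
}

# residue-residue cost matrix: summed squared deviation over the 4 backbone
# atoms of residue i of `a` vs residue j of `b`, after superposition
.dtw_cost <- function(a_bb, b_bb, la, lb) {
  cost <- matrix(0, la, lb)
  for (k in 1:4) {
    ai <- a_bb[seq(k, by = 4, length.out = la), , drop = FALSE]
    bj <- b_bb[seq(k, by = 4, length.out = lb), , drop = FALSE]
    cost <- cost + cross_dist2(ai, bj)
  }
  cost
}

#' Dynamic-time-warping distance between two CDR-H3 loops
#'
#' `a` is first superposed onto `b` on the anchors. For equal-length loops
#' the comparison bypasses the dynamic program and returns the conventional
#' backbone RMSD over aligned residue order (the equal-length limit of the
#' measure). For unequal lengths, the cost of matching residue i to residue
#' j is the summed squared deviation over the four backbone atoms, the
#' optimal monotone path is found by the Needleman-Wunsch-like recurrence
#' `D(i,j) = cost(i,j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1))`, and the
#' distance is `sqrt(total path cost / (4 * path length))` so that units and
#' the equal-length limit are literal RMSD.
#'
#' @param a,b [anchored_loop()] objects.
#' @param superpose superpose `a` onto `b` first (default TRUE; FALSE only
#'   for pre-superposed input).
#' @return list of class `dtw_result` with `distance` (angstrom) and `path`
#'   (matrix of matched residue index pairs, monotone and contiguous).
#' @export
dtw_distance <- function(a, b, superpose = TRUE) {
  if (!inherits(a, "anchored_loop") || !inherits(b, "anchored_loop"))
    stop("inputs must be anchored_loop objects", call. = FALSE)
  if (superpose) a <- anchor_superpose(a, b)
  la <- a$length; lb <- b$length
  if (la == lb) {
    d <- rmsd_coords(a$loop_bb, b$loop_bb)
    path <- cbind(seq_len(la), seq_len(lb))
    return(structure(list(distance = d, path = path), class = "dtw_result"))
  }
  cost <- .dtw_cost(a$loop_bb, b$loop_bb, la, lb)
  D <- matrix(Inf, la + 1, lb + 1)
  D[1, 1] <- 0
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      D[i + 1, j + 1] <- cost[i, j] +
        min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  # backtrace, preferring diagonal then vertical then horizontal
  i <- la; j <- lb; path <- list(c(i, j))
  while (i > 1 || j > 1) {
    choices <- c(diag = if (i > 1 && j > 1) D[i, j] else Inf,
                 vert = if (i > 1) D[i, j + 1] else Inf,
                 horiz = if (j > 1) D[i + 1, j] else Inf)
    step <- names(choices)[which.min(choices)]
    if (step == "diag") { i <- i - 1; j <- j - 1 }
    else if (step == "vert") i <- i - 1
    else j <- j - 1
    path[[length(path) + 1]] <- c(i, j)
  }
  path <- do.call(rbind, rev(path))
  colnames(path) <- c("a", "b")
  total <- D[la + 1, lb + 1]
  structure(list(distance = sqrt(total / (4 * nrow(path))), path = path),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat("<dtw_result> distance ", signif(x$distance, 6), " A, path length ",
      nrow(x$path), "\n", sep = "")
  invisible(x)
}

#' Pairwise DTW distance matrix
#'
#' Symmetric matrix of DTW distances over a list of anchored loops. Each
#' unordered pair is computed once, with the lower-index loop superposed
#' onto the higher-index one. When every loop has the same length and
#' bit-identical anchor coordinates (the regime produced by the loop
#' population generator), anchor superposition is the identity and the
#' matrix is computed in one vectorized pass.
#'
#' @param loops list of [anchored_loop()] objects (>= 2); names or loop ids
#'   become dimnames.
#' @return symmetric numeric matrix with zero diagonal, class
#'   `c("dtw_matrix","matrix")`.
#' @export
pairwise_dtw <- function(loops) {
  n <- length(loops)
  if (n < 2) stop("need at least 2 loops", call. = FALSE)
  ids <- names(loops)
  if (is.null(ids)) {
    ids <- vapply(seq_len(n), function(i) {
      id <- loops[[i]]$id
      if (is.null(id)) paste0("loop", i) else id
    }, character(1))
  }
  lens <- vapply(loops, function(l) l$length, numeric(1))
  same_anchor <- all(vapply(loops, function(l)
    identical(l$anchor_bb, loops[[1]]$anchor_bb), logical(1)))
  if (length(unique(lens)) == 1 && same_anchor) {
    flat <- t(vapply(loops, function(l) as.vector(l$loop_bb),
                     numeric(3 * 4 * lens[1])))
    D <- as.matrix(stats::dist(flat)) / sqrt(4 * lens[1])
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- dtw_distance(loops[[i]], loops[[j]])$distance
      }
    }
  }
  dimnames(D) <- list(ids, ids)
  class(D) <- c("dtw_matrix", "matrix")
  D
}
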