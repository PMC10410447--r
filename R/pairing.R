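# Identical-VH / divergent-VL pair discovery and comparison: greedy
# sequence-identity clustering (cd-hit-style), pair extraction, per-region
# backbone RMSD after VH-framework alignment, Pearson correlation, and the
# canonical-form split with Mann-Whitney U.

.PAIR_REGIONS <- c("CDR-H1", "CDR-H2", "FW-H", "CDR-H3")
.REGION_COLS <- c("CDR-H1" = "rmsd_h1", "CDR-H2" = "rmsd_h2",
                  "FW-H" = "rmsd_fwh", "CDR-H3" = "rmsd_h3")

.aa_submat <- local({
  m <- matrix(-4, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(m) <- 5
  m
})

.check_seq <- function(s, what = "sequence") {
  if (length(s) != 1 || is.na(s) || nchar(s) == 0)
    stop(what, " must be a non-empty string", call. = FALSE)
  if (!grepl("^[A-Z]+$", s))
    stop(what, " contains characters outside the uppercase one-letter alphabet",
         call. = FALSE)
  s
}

#' Global sequence identity
#'
#' Needleman-Wunsch global alignment (match +5, mismatch -4, gap opening
#' cost 10, gap extension 1 per position) via Biostrings, with identity
#' counted as identical aligned positions over the length of the shorter
#' sequence (the cd-hit denominator convention).
#'
#' @param a,b amino-acid sequences (uppercase one-letter strings).
#' @return percent identity in [0, 100].
#' @export
global_identity <- function(a, b) {
  .check_seq(a, "sequence a"); .check_seq(b, "sequence b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = .aa_submat, gapOpening = 10, gapExtension = 1)
  Biostrings::pid(aln, type = "PID3")
}

# identities of one subject sequence against a vector of representatives
.batch_identity <- function(reps, s) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(reps), Biostrings::AAString(s), type = "global",
    substitutionMatrix = .aa_submat, gapOpening = 10, gapExtension = 1)
  Biostrings::pid(aln, type = "PID3")
}

#' Greedy sequence-identity clustering
#'
#' cd-hit-style greedy clustering: sequences are processed in order of
#' decreasing length (ties broken by id for determinism); the first seeds
#' cluster 1, and each subsequent sequence joins the first existing cluster
#' whose representative identity (by [global_identity()]) reaches the
#' threshold, otherwise it seeds a new cluster. A composition bound (the
#' number of aligned matches cannot exceed the per-letter count overlap of
#' the two sequences) screens out representatives that cannot possibly
#' reach the threshold before any alignment is run, in the spirit of
#' cd-hit's word filter; the bound is exact, so results are unchanged.
#'
#' @param seqs named character vector of sequences (names = ids).
#' @param threshold identity threshold as a fraction in (0, 1].
#' @return list of clusters, each a list with `representative` (id),
#'   `members` (ids in joining order).
#' @export
greedy_cluster <- function(seqs, threshold) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names", call. = FALSE)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  cutoff <- threshold * 100 - 1e-9
  comp <- function(s) tabulate(match(strsplit(s, "")[[1]], LETTERS), 26L)
  comps <- vapply(seqs, comp, integer(26))        # 26 x n
  rep_seqs <- character(0)
  rep_comp <- matrix(0L, 26, 0)
  clusters <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]; id <- names(seqs)[i]
    hit <- 0L
    if (length(rep_seqs)) {
      exact <- which(rep_seqs == s)
      if (length(exact)) hit <- exact[1]
      else {
        # upper bound on identity: aligned matches <= composition overlap
        overlap <- colSums(pmin(rep_comp, comps[, i]))
        bound <- 100 * overlap / pmin(nchar(rep_seqs), nchar(s))
        cand <- which(bound >= cutoff)
        if (length(cand)) {
          ident <- .batch_identity(rep_seqs[cand], s)
          ok <- cand[ident >= cutoff]
          if (length(ok)) hit <- ok[1]
        }
      }
    }
    if (hit > 0L) {
      clusters[[hit]]$members <- c(clusters[[hit]]$members, id)
    } else {
      clusters[[length(clusters) + 1]] <- list(representative = id,
                                               members = id)
      rep_seqs <- c(rep_seqs, s)
      rep_comp <- cbind(rep_comp, comps[, i])
    }
  }
  clusters
}

#' Build a sequence record
#'
#' One antibody entry for the pairing analysis: its VH and VL sequences,
#' the structure, and the VL CDR canonical-form labels.
#'
#' @param id identifier.
#' @param vh_seq,vl_seq amino-acid sequences.
#' @param structure an [fv_structure()] (may be `NULL` for sequence-only
#'   clustering).
#' @param vl_forms named list of VL canonical-form labels (e.g.
#'   `list(l1 = "L1-7-A", l2 = "L2-3-A", l3 = "L3-9-A")`).
#' @return list of class `sequence_record`.
#' @export
sequence_record <- function(id, vh_seq, vl_seq, structure = NULL,
                            vl_forms = list()) {
  .check_seq(vh_seq, "vh_seq"); .check_seq(vl_seq, "vl_seq")
  structure(list(id = id, vh_seq = vh_seq, vl_seq = vl_seq,
                 structure = structure, vl_forms = vl_forms),
            class = "sequence_record")
}

#' Extract identical-VH / divergent-VL pairs
#'
#' Clusters records on VH sequences at `vh_threshold` (default 1.0,
#' identical-VH groups), discards singleton clusters, re-clusters each
#' group on VL sequences at `vl_threshold` (default 0.4), and emits every
#' unordered pair within a VL subcluster whose VL identity is below
#' `identity_max` percent (default 99, so near-identical VL pairs are
#' excluded).
#'
#' @param records list of [sequence_record()] objects (>= 2).
#' @param vh_threshold,vl_threshold clustering thresholds (fractions).
#' @param identity_max VL identity upper bound in percent.
#' @return data.frame with `id_a`, `id_b`, `vl_identity` (ids ordered
#'   alphabetically within each pair, rows sorted).
#' @export
extract_pairs <- function(records, vh_threshold = 1.0, vl_threshold = 0.4,
                          identity_max = 99) {
  if (length(records) < 2) stop("need at least 2 records", call. = FALSE)
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate record ids", call. = FALSE)
  names(records) <- ids
  vh <- vapply(records, function(r) r$vh_seq, character(1))
  vl <- vapply(records, function(r) r$vl_seq, character(1))
  vh_cl <- greedy_cluster(vh, vh_threshold)
  out <- list()
  for (cl in vh_cl) {
    if (length(cl$members) < 2) next
    vl_cl <- greedy_cluster(vl[cl$members], vl_threshold)
    for (sub in vl_cl) {
      mem <- sort(sub$members)
      if (length(mem) < 2) next
      for (i in seq_len(length(mem) - 1)) {
        for (j in (i + 1):length(mem)) {
          ident <- global_identity(vl[[mem[i]]], vl[[mem[j]]])
          if (ident < identity_max)
            out[[length(out) + 1]] <- data.frame(
              id_a = mem[i], id_b = mem[j], vl_identity = ident,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(id_a = character(0), id_b = character(0),
                      vl_identity = numeric(0)))
  res <- do.call(rbind, out)
  res <- unique(res)
  res <- res[order(res$id_a, res$id_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-region backbone RMSD of a VH-identical structure pair
#'
#' Aligns structure `b` onto structure `a` on the heavy-chain framework
#' backbone ([kabsch()] on FW-H), then reports backbone RMSD — without
#' re-superposition — for CDR-H1, CDR-H2, FW-H and CDR-H3. Residue sets
#' must match over the compared regions (guaranteed for identical VH
#' sequences).
#'
#' @param a,b [fv_structure()] objects.
#' @param regions regions to report (default CDR-H1/CDR-H2/FW-H/CDR-H3).
#' @return named numeric vector of RMSDs in angstrom.
#' @export
pair_region_rmsd <- function(a, b, regions = .PAIR_REGIONS) {
  grab <- function(fv, label) {
    at <- fv$atoms[fv$atoms$chain == "H" & fv$atoms$atom %in% .BACKBONE, ,
                   drop = FALSE]
    at <- at[assign_region(at$imgt_number, "H") == label, , drop = FALSE]
    key <- paste(at$imgt_number, at$imgt_insertion, at$atom)
    at <- at[order(imgt_order_key(at$imgt_number, at$imgt_insertion),
                   match(at$atom, .BACKBONE)), , drop = FALSE]
    list(key = paste(at$imgt_number, at$imgt_insertion, at$atom),
         coords = as.matrix(at[, c("x", "y", "z")]))
  }
  fa <- grab(a, "FW-H"); fb <- grab(b, "FW-H")
  if (!identical(fa$key, fb$key))
    stop("mismatched FW-H residue sets between ", a$id, " and ", b$id,
         call. = FALSE)
  tf <- kabsch(fb$coords, fa$coords)
  out <- vapply(regions, function(reg) {
    ra <- grab(a, reg); rb <- grab(b, reg)
    if (!identical(ra$key, rb$key))
      stop("mismatched ", reg, " residue sets between ", a$id, " and ", b$id,
           call. = FALSE)
    rmsd_coords(ra$coords, transform_coords(rb$coords, tf))
  }, numeric(1))
  names(out) <- regions
  out
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation between two vectors with the usual two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Canonical-form split test on pair RMSDs
#'
#' Splits pairs into those whose VL canonical forms are all identical
#' (`forms_equal`) and those with at least one changed form, and compares a
#' region's RMSD between the groups: mean difference (different minus
#' equal) and a two-sided Mann-Whitney U test (exact when both groups have
#' at most 20 observations and no ties, normal approximation with tie
#' correction otherwise, as implemented by [stats::wilcox.test()]).
#'
#' @param pairs data.frame with logical `forms_equal` and a `rmsd_<region>`
#'   column (as produced by [pairing_analysis()]), or supply `values` +
#'   `forms_equal` directly via the `...` interface of the columns.
#' @param region region label, e.g. `"CDR-H3"`.
#' @return list with `mean_diff` (angstrom), `U`, `p`, group sizes
#'   `n_equal`, `n_diff`.
#' @export
forms_split_test <- function(pairs, region = "CDR-H3") {
  col <- unname(.REGION_COLS[region])
  if (is.na(col)) stop("unknown region: ", region, call. = FALSE)
  if (!col %in% names(pairs))
    stop("column ", col, " absent from pairs table", call. = FALSE)
  if (!"forms_equal" %in% names(pairs))
    stop("pairs table lacks forms_equal", call. = FALSE)
  x_diff <- pairs[[col]][!pairs$forms_equal]
  x_eq <- pairs[[col]][pairs$forms_equal]
  if (length(x_diff) == 0 || length(x_eq) == 0)
    stop("both canonical-form groups must be non-empty", call. = FALSE)
  exact <- length(x_diff) <= 20 && length(x_eq) <= 20 &&
    !anyDuplicated(c(x_diff, x_eq))
  wt <- stats::wilcox.test(x_diff, x_eq, alternative = "two.sided",
                           exact = exact, correct = !exact)
  list(mean_diff = mean(x_diff) - mean(x_eq), U = unname(wt$statistic),
       p = wt$p.value, n_equal = length(x_eq), n_diff = length(x_diff))
}

#' Full pairing analysis
#'
#' Runs [extract_pairs()] (unless a pair table is supplied), computes
#' per-region backbone RMSDs after VH-framework alignment for every pair,
#' flags whether all VL canonical forms are identical within the pair, and
#' reports Pearson correlations of VL identity against each region's RMSD
#' plus the canonical-form split test per region.
#'
#' @param records list of [sequence_record()] objects carrying structures.
#' @param pairs optional precomputed pair table from [extract_pairs()].
#' @param ... passed to [extract_pairs()].
#' @return list of class `pairing_result`: `pairs` (data.frame with
#'   `id_a`, `id_b`, `vl_identity`, `rmsd_*`, `forms_equal`),
#'   `correlations` (data.frame `region`, `r`, `p`, `n`), `split`
#'   (data.frame `region`, `mean_diff`, `U`, `p`).
#' @export
pairing_analysis <- function(records, pairs = NULL, ...) {
  ids <- vapply(records, function(r) r$id, character(1))
  names(records) <- ids
  if (is.null(pairs)) pairs <- extract_pairs(records, ...)
  if (nrow(pairs) == 0) stop("no qualifying pairs", call. = FALSE)
  cols <- unname(.REGION_COLS[.PAIR_REGIONS])
  rms <- t(vapply(seq_len(nrow(pairs)), function(i) {
    pair_region_rmsd(records[[pairs$id_a[i]]]$structure,
                     records[[pairs$id_b[i]]]$structure)
  }, numeric(length(.PAIR_REGIONS))))
  colnames(rms) <- cols
  forms_equal <- vapply(seq_len(nrow(pairs)), function(i) {
    fa <- records[[pairs$id_a[i]]]$vl_forms
    fb <- records[[pairs$id_b[i]]]$vl_forms
    keys <- union(names(fa), names(fb))
    all(vapply(keys, function(k)
      identical(fa[[k]], fb[[k]]), logical(1)))
  }, logical(1))
  pairs <- cbind(pairs, as.data.frame(rms), forms_equal = forms_equal)
  correlations <- do.call(rbind, lapply(seq_along(.PAIR_REGIONS), function(k) {
    pc <- tryCatch(pearson_cor(pairs$vl_identity, pairs[[cols[k]]]),
                   error = function(e) list(r = NA_real_, p = NA_real_,
                                            n = nrow(pairs)))
    data.frame(region = .PAIR_REGIONS[k], r = pc$r, p = pc$p, n = pc$n,
               stringsAsFactors = FALSE)
  }))
  split <- if (any(forms_equal) && any(!forms_equal)) {
    do.call(rbind, lapply(seq_along(.PAIR_REGIONS), function(k) {
      st <- forms_split_test(pairs, .PAIR_REGIONS[k])
      data.frame(region = .PAIR_REGIONS[k], mean_diff = st$mean_diff,
                 U = st$U, p = st$p, stringsAsFactors = FALSE)
    }))
  } else NULL
  structure(list(pairs = pairs, correlations = correlations, split = split),
            class = "pairing_result")
}

#' @export
print.pairing_result <- function(x, ...) {
  cat("<pairing_result> ", nrow(x$pairs), " pairs\n", sep = "")
  h3 <- x$correlations[x$correlations$region == "CDR-H3", ]
  cat("  VL identity vs CDR-H3 RMSD: r = ", signif(h3$r, 3),
      ", p = ", signif(h3$p, 3), "\n", sep = "")
  invisible(x)
}
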