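# Post-processing of biased (metadynamics) conformational ensembles:
# time-independent reweighting, per-loop RMSD series, RMSF, native-pose
# fractions and average-linkage frame clustering.

#' Construct a conformational ensemble
#'
#' Frames are stored bio3d-style as an F x (3A) coordinate matrix; the atom
#' map ties each atom column triple to a chain, IMGT position and atom name.
#'
#' @param xyz numeric F x (3A) matrix (columns x1,y1,z1,x2,...).
#' @param atom_map data.frame with columns `chain`, `imgt_number`,
#'   `imgt_insertion`, `atom`, `element` (one row per atom, same order as
#'   the coordinate triples).
#' @param bias optional per-frame bias energy V(s) in kJ/mol (length F).
#' @param temperature simulation temperature in kelvin (default 300).
#' @param reference reference frame index, default 1 (the conformation at
#'   the beginning of the simulation).
#' @return object of class `fv_ensemble`.
#' @export
fv_ensemble <- function(xyz, atom_map, bias = NULL, temperature = 300,
                        reference = 1L) {
  if (!is.matrix(xyz) || ncol(xyz) %% 3 != 0)
    stop("xyz must be an F x (3A) matrix", call. = FALSE)
  if (nrow(atom_map) != ncol(xyz) / 3)
    stop("atom_map rows must match the atom count", call. = FALSE)
  if (!is.null(bias)) {
    if (length(bias) != nrow(xyz)) stop("bias length must equal frame count",
                                        call. = FALSE)
    if (!all(is.finite(bias))) stop("bias must be finite", call. = FALSE)
  }
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  structure(list(xyz = xyz, atom_map = atom_map, bias = bias,
                 temperature = temperature, reference = as.integer(reference)),
            class = "fv_ensemble")
}

#' @export
print.fv_ensemble <- function(x, ...) {
  cat("<fv_ensemble> ", nrow(x$xyz), " frames x ", nrow(x$atom_map),
      " atoms", if (!is.null(x$bias)) ", biased", ", T = ", x$temperature,
      " K\n", sep = "")
  invisible(x)
}

.frame_coords <- function(ens, frame, rows = NULL) {
  v <- ens$xyz[frame, ]
  m <- matrix(v, ncol = 3, byrow = TRUE)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

# atom-map row indices of a region's atoms for one chain
.map_rows <- function(atom_map, label, atom_set = c("backbone", "heavy")) {
  atom_set <- match.arg(atom_set)
  pl <- parse_region_label(label)
  sel <- atom_map$chain == pl$chain &
    assign_region(atom_map$imgt_number, pl$chain) == label
  if (atom_set == "backbone") sel <- sel & atom_map$atom %in% .BACKBONE
  else sel <- sel & .is_heavy_atom(atom_map$element)
  which(sel)
}

#' Time-independent metadynamics reweighting
#'
#' Recovers unbiased frame weights from the deposited bias:
#' `w(s) proportional to exp(V(s) / (kB * T))`, normalized to sum 1. The
#' maximum bias is subtracted before exponentiation for overflow safety;
#' weights are invariant to any constant shift of the bias. kB is taken in
#' kJ/(mol K) to match bias energies in kJ/mol.
#'
#' @param bias per-frame bias V(s) in kJ/mol, or an `fv_ensemble` carrying
#'   one.
#' @param temperature temperature in kelvin (ignored when an ensemble is
#'   given).
#' @return numeric vector of normalized weights (class `frame_weights`).
#' @export
reweight <- function(bias, temperature = 300) {
  if (inherits(bias, "fv_ensemble")) {
    temperature <- bias$temperature
    if (is.null(bias$bias)) {
      w <- rep(1 / nrow(bias$xyz), nrow(bias$xyz))
      return(structure(w, class = "frame_weights"))
    }
    bias <- bias$bias
  }
  if (!all(is.finite(bias))) stop("bias must be finite", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  lw <- bias / (.kB * temperature)
  w <- exp(lw - max(lw))
  structure(w / sum(w), class = "frame_weights")
}

#' Per-frame loop RMSD series
#'
#' For every frame, the flank backbone (the `anchor_width` residues on
#' either side of the loop, in IMGT chain order) is superposed onto the
#' reference frame's flank backbone, and the backbone RMSD of the loop
#' against the reference is recorded. The reference defaults to the
#' conformation at the beginning of the simulation (frame 1); an external
#' reference (e.g. a crystal structure) may be supplied as a coordinate
#' matrix over the same atom map.
#'
#' @param ens an [fv_ensemble()].
#' @param label loop region label, e.g. `"CDR-H3"`.
#' @param anchor_width flank width in residues (default 3).
#' @param ref_coords optional A x 3 matrix replacing the reference frame.
#' @return numeric vector of per-frame RMSDs in angstrom.
#' @export
loop_rmsd_series <- function(ens, label, anchor_width = 3L,
                             ref_coords = NULL) {
  map <- ens$atom_map
  pl <- parse_region_label(label)
  chain_rows <- which(map$chain == pl$chain & map$atom %in% .BACKBONE)
  cm <- map[chain_rows, , drop = FALSE]
  key <- imgt_order_key(cm$imgt_number, cm$imgt_insertion)
  res_keys <- unique(key[order(key)])
  loop_keys <- sort(unique(key[assign_region(cm$imgt_number, pl$chain) == label]))
  if (length(loop_keys) == 0) stop("loop absent from atom map", call. = FALSE)
  pos <- match(loop_keys, res_keys)
  lo <- min(pos); hi <- max(pos)
  if (lo - anchor_width < 1 || hi + anchor_width > length(res_keys))
    stop("missing ", anchor_width, "-residue flanks for ", label,
         call. = FALSE)
  flank_keys <- res_keys[c((lo - anchor_width):(lo - 1),
                           (hi + 1):(hi + anchor_width))]
  loop_rows <- chain_rows[key %in% loop_keys]
  flank_rows <- chain_rows[key %in% flank_keys]
  ref <- if (is.null(ref_coords)) {
    list(loop = .frame_coords(ens, ens$reference, loop_rows),
         flank = .frame_coords(ens, ens$reference, flank_rows))
  } else {
    list(loop = ref_coords[loop_rows, , drop = FALSE],
         flank = ref_coords[flank_rows, , drop = FALSE])
  }
  vapply(seq_len(nrow(ens$xyz)), function(f) {
    tf <- kabsch(.frame_coords(ens, f, flank_rows), ref$flank)
    rmsd_coords(transform_coords(.frame_coords(ens, f, loop_rows), tf),
                ref$loop)
  }, numeric(1))
}

#' Root-mean-square fluctuation of a loop
#'
#' Defined here as the (weight-) time average of the per-frame RMSD series
#' relative to the reference conformation — not the crystallographic
#' sqrt-of-mean-square-fluctuation. With uniform weights it is the plain
#' arithmetic mean of the series.
#'
#' @param series per-frame RMSD values (e.g. [loop_rmsd_series()]).
#' @param weights per-frame weights (e.g. [reweight()]); default uniform.
#' @return weighted mean RMSD in angstrom.
#' @export
rmsf <- function(series, weights = NULL) {
  if (is.null(weights)) weights <- rep(1 / length(series), length(series))
  if (length(series) != length(weights))
    stop("series and weights differ in length", call. = FALSE)
  sum(weights * series) / sum(weights)
}

#' Fraction of frames in the native conformation
#'
#' Total weight of frames whose loop RMSD from the reference is within the
#' cutoff (default 1 angstrom, the conventional bound for calling two loop
#' conformations the same).
#'
#' @inheritParams rmsf
#' @param cutoff RMSD cutoff in angstrom (default 1.0).
#' @return fraction in [0, 1].
#' @export
native_fraction <- function(series, weights = NULL, cutoff = 1.0) {
  if (is.null(weights)) weights <- rep(1 / length(series), length(series))
  if (length(series) != length(weights))
    stop("series and weights differ in length", call. = FALSE)
  sum(weights[series <= cutoff]) / sum(weights)
}

#' Average-linkage clustering of ensemble frames
#'
#' Frames are superposed on the reference frame using the framework
#' backbone, excluding the first two framework residues of each chain's
#' N-terminus (the termini are considerably more flexible than the rest of
#' the framework). The inter-frame feature distance is the joint backbone
#' RMSD over all six CDRs; frames are then merged by agglomerative
#' average-linkage clustering and flat clusters are cut at `cutoff`
#' (default 1.25 angstrom). Each cluster's representative is its medoid
#' (minimum summed within-cluster distance). A per-loop feature
#' (`feature = "CDR-H3"` etc.) is exposed as an option.
#'
#' @param ens an [fv_ensemble()].
#' @param cutoff flat-cluster height in angstrom.
#' @param feature `"joint"` (all six CDRs, default) or a single region
#'   label.
#' @param exclude_nterm framework residues dropped from each chain's
#'   N-terminus before alignment (default 2).
#' @return list of class `frame_clustering`: `labels` (per-frame cluster
#'   id), `representatives` (per-cluster medoid frame index), `cutoff`,
#'   `hclust` (the merge tree), `dist` (frame-frame RMSD, class `dist`).
#' @export
cluster_frames <- function(ens, cutoff = 1.25, feature = "joint",
                           exclude_nterm = 2L) {
  map <- ens$atom_map
  nf <- nrow(ens$xyz)
  if (nf == 1) {
    return(structure(list(labels = 1L, representatives = 1L, cutoff = cutoff,
                          hclust = NULL, dist = NULL),
                     class = "frame_clustering"))
  }
  fw_rows <- integer(0)
  for (ch in c("H", "L")) {
    rows <- which(map$chain == ch & map$atom %in% .BACKBONE &
                    assign_region(map$imgt_number, ch) == paste0("FW-", ch))
    key <- imgt_order_key(map$imgt_number[rows], map$imgt_insertion[rows])
    res <- sort(unique(key))
    drop <- res[seq_len(min(exclude_nterm, length(res)))]
    fw_rows <- c(fw_rows, rows[!(key %in% drop)])
  }
  cdr_rows <- if (identical(feature, "joint")) {
    unlist(lapply(cdr_labels(), function(l) .map_rows(map, l, "backbone")))
  } else .map_rows(map, feature, "backbone")
  ref_fw <- .frame_coords(ens, ens$reference, fw_rows)
  feat <- t(vapply(seq_len(nf), function(f) {
    tf <- kabsch(.frame_coords(ens, f, fw_rows), ref_fw)
    as.vector(transform_coords(.frame_coords(ens, f, cdr_rows), tf))
  }, numeric(3 * length(cdr_rows))))
  d <- stats::dist(feat) / sqrt(length(cdr_rows))
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, h = cutoff)
  dm <- as.matrix(d)
  reps <- vapply(sort(unique(labels)), function(k) {
    idx <- which(labels == k)
    idx[which.min(rowSums(dm[idx, idx, drop = FALSE]))]
  }, integer(1))
  structure(list(labels = labels, representatives = reps, cutoff = cutoff,
                 hclust = hc, dist = d),
            class = "frame_clustering")
}

#' @export
print.frame_clustering <- function(x, ...) {
  cat("<frame_clustering> ", length(x$labels), " frames -> ",
      length(x$representatives), " clusters at ", x$cutoff, " A\n", sep = "")
  invisible(x)
}
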