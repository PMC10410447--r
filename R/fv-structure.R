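# The Fv domain model: an IMGT-numbered heavy/light chain pair with
# heavy-atom coordinates and structure-level metadata.

#' Construct an Fv structure
#'
#' The container used throughout the package: one antibody Fv, i.e. a paired
#' heavy and light variable domain, with every atom carried in a single
#' atom table (one row per atom) and IMGT numbering. Residues are sorted by
#' chain (H before L) and by IMGT order (including the CDR3 insertion
#' convention, see [imgt_order_key()]).
#'
#' @param id structure identifier.
#' @param atoms data.frame with columns `chain` ("H"/"L"), `imgt_number`,
#'   `imgt_insertion`, `aa` (one-letter residue code), `atom` (atom name),
#'   `element` (element symbol), `x`, `y`, `z` (angstrom).
#' @param metadata list with any of `method`, `resolution`, `subtype`
#'   ("kappa"/"lambda"/"unknown"), `vh_gene`, `vl_gene`, `canonical_forms`
#'   (named list, e.g. `list(l1 = "L1-7-A")`).
#' @return an object of class `fv_structure`.
#' @export
fv_structure <- function(id, atoms, metadata = list()) {
  need <- c("chain", "imgt_number", "imgt_insertion", "aa", "atom",
            "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  atoms$chain <- toupper(as.character(atoms$chain))
  if (!all(atoms$chain %in% c("H", "L")))
    stop("chain must be 'H' or 'L'", call. = FALSE)
  atoms$imgt_number <- as.integer(atoms$imgt_number)
  atoms$imgt_insertion <- as.integer(atoms$imgt_insertion)
  bad <- atoms$imgt_number < .IMGT_MIN | atoms$imgt_number > .IMGT_MAX
  if (any(bad)) stop("IMGT numbers outside [1,128] in structure ", id,
                     call. = FALSE)
  key <- imgt_order_key(atoms$imgt_number, atoms$imgt_insertion)
  ord <- order(match(atoms$chain, c("H", "L")), key, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  # duplicate-position guard: one residue per (chain, number, insertion)
  rk <- paste(atoms$chain, atoms$imgt_number, atoms$imgt_insertion)
  aa_per_res <- tapply(atoms$atom, rk, function(a) anyDuplicated(a))
  if (any(aa_per_res > 0))
    stop("duplicate atoms within a residue in structure ", id, call. = FALSE)
  md <- utils::modifyList(
    list(method = NA_character_, resolution = NA_real_, subtype = "unknown",
         vh_gene = NA_character_, vl_gene = NA_character_,
         canonical_forms = list()),
    metadata)
  structure(list(id = id, atoms = atoms, metadata = md),
            class = "fv_structure")
}

#' @export
print.fv_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "imgt_number", "imgt_insertion")]))
  cat("<fv_structure> ", x$id, ": ", nres, " residues, ",
      nrow(x$atoms), " atoms (",
      sum(x$atoms$chain == "H"), " H / ", sum(x$atoms$chain == "L"), " L)\n",
      sep = "")
  invisible(x)
}

.is_heavy_atom <- function(element) !(toupper(element) %in% c("H", "D"))
.BACKBONE <- c("N", "CA", "C", "O")

#' Residue table of one chain
#'
#' One row per residue of the requested chain, in IMGT order.
#' @param fv an [fv_structure()].
#' @param chain `"H"` or `"L"`.
#' @return data.frame with `imgt_number`, `imgt_insertion`, `aa`, `region`.
#' @export
fv_residues <- function(fv, chain) {
  a <- fv$atoms[fv$atoms$chain == chain, , drop = FALSE]
  r <- unique(a[, c("imgt_number", "imgt_insertion", "aa")])
  rownames(r) <- NULL
  r$region <- assign_region(r$imgt_number, chain)
  r
}

#' One-letter amino-acid sequence of a chain
#' @inheritParams fv_residues
#' @return character scalar.
#' @export
fv_sequence <- function(fv, chain) {
  paste(fv_residues(fv, chain)$aa, collapse = "")
}

#' Select the atoms of one region
#'
#' Extracts the atoms of all residues assigned to a CDR or framework region,
#' in chain (IMGT) order. The heavy set is every non-hydrogen atom; the
#' backbone set is N, CA, C, O where present.
#'
#' @param fv an [fv_structure()].
#' @param label region label, e.g. `"CDR-H3"` (see [region_label()]).
#' @param atom_set `"heavy"` or `"backbone"`.
#' @return object of class `loop_selection`: list with `label`, `atom_set`,
#'   `coords` (N x 3 matrix), and the atom table subset `atoms`.
#' @export
select_loop <- function(fv, label, atom_set = c("heavy", "backbone")) {
  atom_set <- match.arg(atom_set)
  pl <- parse_region_label(label)
  a <- fv$atoms[fv$atoms$chain == pl$chain, , drop = FALSE]
  reg <- assign_region(a$imgt_number, pl$chain)
  a <- a[reg == label, , drop = FALSE]
  a <- if (atom_set == "heavy") a[.is_heavy_atom(a$element), , drop = FALSE]
       else a[a$atom %in% .BACKBONE, , drop = FALSE]
  structure(list(label = label, atom_set = atom_set,
                 coords = as.matrix(a[, c("x", "y", "z")]),
                 atoms = a),
            class = "loop_selection")
}

#' @export
print.loop_selection <- function(x, ...) {
  cat("<loop_selection> ", x$label, " (", x$atom_set, "): ",
      nrow(x$coords), " atoms\n", sep = "")
  invisible(x)
}
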