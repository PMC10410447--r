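# File interfaces: PDB reading/writing (via bio3d), the IMGT numbering map,
# the per-structure metadata table, multi-model ensemble PDBs and bias
# files. The "pre-numbered" PDB dialect has chain ids H/L and residue
# numbers equal to IMGT numbers (insertion codes A, B, ... for insertion
# ranks 1, 2, ...); this is the dialect the synthetic writers emit.

.ins_to_code <- function(ins) ifelse(ins == 0, "", LETTERS[pmin(ins, 26L)])
.code_to_ins <- function(code) {
  code <- trimws(ifelse(is.na(code), "", code))
  ifelse(code == "", 0L, match(toupper(code), LETTERS))
}

#' Write an Fv structure as a pre-numbered PDB file
#'
#' Emits chain ids H/L with residue numbers equal to IMGT numbers and
#' insertion ranks as PDB insertion codes.
#'
#' @param fv an [fv_structure()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fv_pdb <- function(fv, path) {
  a <- fv$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$imgt_number,
                   insert = .ins_to_code(a$imgt_insertion),
                   resid = bio3d::aa123(a$aa),
                   chain = a$chain,
                   eleno = seq_len(nrow(a)),
                   elety = a$atom,
                   elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

# altloc resolution on a bio3d atom table: keep highest occupancy per
# (chain, resno, insert, elety); ties -> first in file order
.resolve_altloc <- function(at) {
  at <- at[at$type == "ATOM", , drop = FALSE]
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety)
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
    ix[which.max(occ[ix])]
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

#' Read an Fv structure from a PDB file
#'
#' HETATM records are ignored; alternate locations keep the
#' highest-occupancy atom (ties resolved by file order). With
#' `numbering = NULL` the file is taken to be in the pre-numbered dialect
#' (chains H/L, residue numbers already IMGT). Otherwise `numbering` maps
#' author numbering to IMGT: a data.frame with columns `chain_id`,
#' `author_resid`, `author_icode`, `imgt_number`, `imgt_insertion`
#' (see [read_numbering_map()]); atoms without a map entry are dropped.
#' Only the first heavy/light chain pair encountered in file order is kept:
#' the chain labelled `H` (or the first mapped chain) becomes the heavy
#' chain and the chain labelled `L` (or the second) the light chain. When
#' both domains map onto a single author chain the structure is flagged as
#' a single-chain construct (`metadata$scfv`).
#'
#' @param path PDB file.
#' @param id structure id (default: file name without extension).
#' @param numbering optional numbering map data.frame.
#' @param metadata metadata list merged into the structure (see
#'   [fv_structure()]).
#' @return an [fv_structure()].
#' @export
read_fv_pdb <- function(path, id = NULL, numbering = NULL, metadata = list()) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- .resolve_altloc(pdb$atom)
  if (is.null(numbering)) {
    at <- at[at$chain %in% c("H", "L"), , drop = FALSE]
    at$fv_chain <- at$chain
    at$imgt_number <- at$resno
    at$imgt_insertion <- .code_to_ins(at$insert)
  } else {
    key_at <- paste(at$chain, at$resno,
                    trimws(ifelse(is.na(at$insert), "", at$insert)))
    key_map <- paste(numbering$chain_id, numbering$author_resid,
                     trimws(ifelse(is.na(numbering$author_icode), "",
                                   numbering$author_icode)))
    hit <- match(key_at, key_map)
    at <- at[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
    at$imgt_number <- numbering$imgt_number[hit]
    at$imgt_insertion <- as.integer(numbering$imgt_insertion[hit])
    # chain roles: explicit H/L author chains win, else first two mapped
    # chains in file order
    chains <- unique(at$chain)
    hv <- if ("H" %in% chains) "H" else chains[1]
    lt <- if ("L" %in% chains) "L" else if (length(chains) >= 2)
      setdiff(chains, hv)[1] else NA
    if (identical(hv, lt) || length(chains) == 1) metadata$scfv <- TRUE
    at$fv_chain <- ifelse(at$chain == hv, "H",
                          ifelse(!is.na(lt) & at$chain == lt, "L", NA))
    at <- at[!is.na(at$fv_chain), , drop = FALSE]
  }
  if (nrow(at) == 0) stop("no mappable ATOM records in ", path, call. = FALSE)
  elem <- at$elesy
  elem[is.na(elem) | trimws(elem) == ""] <-
    substr(gsub("[0-9]", "", at$elety[is.na(elem) | trimws(elem) == ""]), 1, 1)
  atoms <- data.frame(chain = at$fv_chain,
                      imgt_number = at$imgt_number,
                      imgt_insertion = at$imgt_insertion,
                      aa = bio3d::aa321(at$resid),
                      atom = at$elety,
                      element = trimws(elem),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  fv_structure(id, atoms, metadata)
}

#' Read an IMGT numbering map
#'
#' CSV with columns `chain_id`, `author_resid`, `author_icode`,
#' `imgt_number`, `imgt_insertion`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_numbering_map <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(author_icode = "character"))
  need <- c("chain_id", "author_resid", "author_icode", "imgt_number",
            "imgt_insertion")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("numbering map lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  m
}

#' Read a structure metadata table
#'
#' CSV with columns `id`, `method`, `resolution`, `subtype`, `vh_gene`,
#' `vl_gene`, `h1_form`, `h2_form`, `l1_form`, `l3_form` (and optionally
#' `l2_form`).
#'
#' @param path CSV file.
#' @return named list of metadata lists keyed by id, ready for
#'   [fv_structure()]/[read_fv_pdb()].
#' @export
read_metadata_csv <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(m)) stop("metadata table lacks an id column",
                                call. = FALSE)
  out <- lapply(seq_len(nrow(m)), function(i) {
    r <- as.list(m[i, , drop = FALSE])
    forms <- r[grepl("_form$", names(r))]
    names(forms) <- sub("_form$", "", names(forms))
    list(method = r$method, resolution = suppressWarnings(as.numeric(r$resolution)),
         subtype = if (is.null(r$subtype)) "unknown" else r$subtype,
         vh_gene = r$vh_gene, vl_gene = r$vl_gene,
         canonical_forms = forms[!vapply(forms, is.null, logical(1))])
  })
  names(out) <- m$id
  out
}

#' Write a metadata table for a structure list
#' @param structures list of [fv_structure()] objects.
#' @param path CSV output file.
#' @return `path`, invisibly.
#' @export
write_metadata_csv <- function(structures, path) {
  rows <- lapply(structures, function(s) {
    md <- s$metadata
    cf <- md$canonical_forms
    data.frame(id = s$id, method = md$method, resolution = md$resolution,
               subtype = md$subtype, vh_gene = md$vh_gene,
               vl_gene = md$vl_gene,
               h1_form = if (is.null(cf$h1)) "" else cf$h1,
               h2_form = if (is.null(cf$h2)) "" else cf$h2,
               l1_form = if (is.null(cf$l1)) "" else cf$l1,
               l2_form = if (is.null(cf$l2)) "" else cf$l2,
               l3_form = if (is.null(cf$l3)) "" else cf$l3,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an ensemble as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame in the pre-numbered dialect.
#'
#' @param ens an [fv_ensemble()].
#' @param path output file.
#' @param frames frame indices (default all).
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nrow(ens$xyz))
  map <- ens$atom_map
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE, after = FALSE)
  for (k in seq_along(frames)) {
    f <- frames[k]
    bio3d::write.pdb(file = tmp, xyz = ens$xyz[f, ],
                     type = rep("ATOM", nrow(map)),
                     resno = map$imgt_number,
                     insert = .ins_to_code(map$imgt_insertion),
                     resid = bio3d::aa123(if (is.null(map$aa)) rep("A", nrow(map)) else map$aa),
                     chain = map$chain, eleno = seq_len(nrow(map)),
                     elety = map$atom, elesy = map$element,
                     o = rep(1, nrow(map)), b = rep(0, nrow(map)), end = FALSE)
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(readLines(tmp), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB into an ensemble
#'
#' Expects the pre-numbered dialect. Bias energies, when given, are read
#' from a single-column text file (kJ/mol, one value per frame).
#'
#' @param path multi-model PDB file.
#' @param bias_path optional bias file.
#' @param temperature kelvin.
#' @return an [fv_ensemble()].
#' @export
read_ensemble_pdb <- function(path, bias_path = NULL, temperature = 300) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  elem <- at$elesy
  elem[is.na(elem) | trimws(elem) == ""] <-
    substr(gsub("[0-9]", "", at$elety[is.na(elem) | trimws(elem) == ""]), 1, 1)
  map <- data.frame(chain = at$chain, imgt_number = at$resno,
                    imgt_insertion = .code_to_ins(at$insert),
                    aa = bio3d::aa321(at$resid), atom = at$elety,
                    element = trimws(elem), stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  bias <- if (!is.null(bias_path)) scan(bias_path, quiet = TRUE) else NULL
  fv_ensemble(xyz, map, bias = bias, temperature = temperature)
}

#' Write per-frame bias energies to a text file
#' @param bias numeric vector (kJ/mol).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bias_file <- function(bias, path) {
  writeLines(format(bias, digits = 17, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
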