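# Crystal data-set filtering: the rules used to assemble a non-redundant set
# of X-ray Fv structures with fully resolved CDR loops.

#' Filter a crystal structure set
#'
#' Applies, in order, the inclusion rules for the crystal data set:
#' \enumerate{
#'   \item `method`: X-ray crystallography only (case-insensitive match on
#'     "x-ray"); missing method rejects.
#'   \item `resolution`: at most `max_resolution` angstrom; missing
#'     resolution rejects (conservative).
#'   \item `paired_chains`: both a heavy and a light chain with at least one
#'     residue each.
#'   \item `scfv`: single-chain constructs (flagged by the reader via
#'     `metadata$scfv`) are rejected.
#'   \item `unresolved_loop`: every residue of each of the six CDRs must
#'     carry backbone atoms N, CA and C, and no CDR may be empty.
#'   \item `redundancy`: greedy clustering of the concatenated heavy+light
#'     sequence at `identity_threshold` (fraction); only cluster
#'     representatives are kept.
#' }
#' Rejections are data, not errors: the return value carries a log with one
#' row per rejected structure naming the first rule it failed.
#'
#' @param structures list of [fv_structure()] objects.
#' @param max_resolution resolution cutoff in angstrom (default 3.0).
#' @param identity_threshold redundancy threshold as a fraction (default 0.95).
#' @return list with `kept` (list of structures), `log` (data.frame
#'   `id`, `rule`), and `n_input`.
#' @export
filter_crystal_set <- function(structures, max_resolution = 3.0,
                               identity_threshold = 0.95) {
  ids <- vapply(structures, function(s) s$id, character(1))
  rule <- rep(NA_character_, length(structures))

  for (i in seq_along(structures)) {
    s <- structures[[i]]
    md <- s$metadata
    if (is.null(md$method) || is.na(md$method) ||
        !grepl("x[- ]?ray", md$method, ignore.case = TRUE)) {
      rule[i] <- "method"; next
    }
    if (is.null(md$resolution) || is.na(md$resolution) ||
        md$resolution > max_resolution) {
      rule[i] <- "resolution"; next
    }
    if (!all(c("H", "L") %in% unique(s$atoms$chain))) {
      rule[i] <- "paired_chains"; next
    }
    if (isTRUE(md$scfv)) {
      rule[i] <- "scfv"; next
    }
    if (!.cdrs_resolved(s)) {
      rule[i] <- "unresolved_loop"; next
    }
  }

  keep <- which(is.na(rule))
  if (length(keep) > 1) {
    seqs <- vapply(structures[keep], function(s)
      paste0(fv_sequence(s, "H"), fv_sequence(s, "L")), character(1))
    names(seqs) <- ids[keep]
    cl <- greedy_cluster(seqs, threshold = identity_threshold)
    reps <- vapply(cl, function(x) x$representative, character(1))
    dup <- keep[!(ids[keep] %in% reps)]
    rule[dup] <- "redundancy"
    keep <- which(is.na(rule))
  }

  log <- data.frame(id = ids[!is.na(rule)], rule = rule[!is.na(rule)],
                    stringsAsFactors = FALSE)
  list(kept = structures[keep], log = log, n_input = length(structures))
}

# every CDR residue must have N, CA, C; every CDR non-empty
.cdrs_resolved <- function(s) {
  for (lab in cdr_labels()) {
    pl <- parse_region_label(lab)
    a <- s$atoms[s$atoms$chain == pl$chain, , drop = FALSE]
    a <- a[assign_region(a$imgt_number, pl$chain) == lab, , drop = FALSE]
    if (nrow(a) == 0) return(FALSE)
    rk <- paste(a$imgt_number, a$imgt_insertion)
    for (r in unique(rk)) {
      if (!all(c("N", "CA", "C") %in% a$atom[rk == r])) return(FALSE)
    }
  }
  TRUE
}
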