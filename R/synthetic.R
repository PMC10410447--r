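# Synthetic-data generators with known ground truth: idealized Fv
# structures with controllable inter-loop separations, multi-state biased
# ensembles, loop populations with planted per-stratum diversity offsets,
# and sequence cohorts with planted identical-VH/divergent-VL pairs.
#
# Loop geometry is deliberately pseudo-physical: residues are laid out as
# semicircular arcs with fixed intra-residue atom offsets and 2 pseudo
# side-chain heavy atoms. The analysis layer consumes coordinates only, so
# geometric realism is unnecessary for correctness testing; none of these
# backbones are Ramachandran-valid.

# intra-residue atom offsets (angstrom), relative to the residue center
.ATOM_OFFSETS <- rbind(N  = c(-1.20, 0.35, 0.00),
                       CA = c( 0.00, 0.00, 0.00),
                       C  = c( 1.20, 0.35, 0.00),
                       O  = c( 1.75, 1.45, 0.25),
                       CB = c( 0.00, -0.90, 0.90),
                       CG = c( 0.30, -1.60, 1.70))
.ATOM_ELEMENTS <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C", CG = "C")
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.DEFAULT_LOOP_LENGTHS <- c(H1 = 8L, H2 = 8L, H3 = 13L, L1 = 7L, L2 = 3L,
                           L3 = 9L)
# default loop base centers: two rows of arcs separated along y, CDR3
# loops adjacent at the domain interface
.LOOP_CENTERS <- rbind("CDR-H2" = c(-4, 15, 0),
                       "CDR-H1" = c(-2, 9, 0),
                       "CDR-H3" = c( 0, 3, 0),
                       "CDR-L3" = c( 0, -3, 0),
                       "CDR-L1" = c( 2, -9, 0),
                       "CDR-L2" = c( 4, -15, 0))

# residue centers of an arc of L residues in the x-z plane at height y
.arc_centers <- function(L, center, spacing = 3.8) {
  if (L == 1) return(matrix(center + c(0, 0, 2), 1))
  rho <- max(2, spacing * (L - 1) / pi)
  theta <- pi - pi * (seq_len(L) - 1) / (L - 1)
  cbind(center[1] + rho * cos(theta), center[2],
        center[3] + rho * sin(theta))
}

# atom table for a run of residues at given centers
.residues_atoms <- function(chain, numbers, insertions, aa, centers,
                            atoms = rownames(.ATOM_OFFSETS)) {
  n <- length(numbers)
  per <- length(atoms)
  off <- .ATOM_OFFSETS[atoms, , drop = FALSE]
  xyz <- centers[rep(seq_len(n), each = per), , drop = FALSE] +
    off[rep(seq_len(per), n), , drop = FALSE]
  data.frame(chain = chain,
             imgt_number = rep(numbers, each = per),
             imgt_insertion = rep(insertions, each = per),
             aa = rep(aa, each = per),
             atom = rep(atoms, n),
             element = rep(unname(.ATOM_ELEMENTS[atoms]), n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Specification for a synthetic Fv structure
#'
#' @param loop_lengths named integer vector over `H1`,`H2`,`H3`,`L1`,`L2`,
#'   `L3` (defaults 8, 8, 13, 7, 3, 9 residues, bracketing typical CDR
#'   lengths).
#' @param inter_loop_gap named list of target minimum heavy-atom distances
#'   in angstrom; names are `"CDR-Xi|CDR-Yj"` pairs, e.g.
#'   `list("CDR-H3|CDR-L3" = 4)`. Unnamed pairs keep the default layout.
#' @param seed integer seed; the generator is a pure function of the spec.
#' @param metadata metadata overrides for the emitted structure.
#' @return list of class `fv_spec`.
#' @export
fv_spec <- function(loop_lengths = NULL, inter_loop_gap = list(), seed = 1,
                    metadata = list()) {
  ll <- .DEFAULT_LOOP_LENGTHS
  if (!is.null(loop_lengths)) ll[names(loop_lengths)] <- as.integer(loop_lengths)
  if (any(ll < 1)) stop("loop lengths must be >= 1", call. = FALSE)
  if (length(inter_loop_gap) && any(unlist(inter_loop_gap) <= 0))
    stop("gap targets must be positive", call. = FALSE)
  structure(list(loop_lengths = ll, inter_loop_gap = inter_loop_gap,
                 seed = as.integer(seed), metadata = metadata),
            class = "fv_spec")
}

#' Generate a synthetic Fv structure
#'
#' Builds an idealized two-chain Fv: the full 93 framework positions of each
#' chain along a zigzag path (so anchors IMGT 100-104/118-122 and all
#' 3-residue loop flanks always exist) and the six CDRs as semicircular
#' arcs protruding from per-loop base positions. When minimum-distance
#' targets are given in the spec, loop positions are adjusted iteratively
#' until every realized minimum heavy-atom distance (measured with
#' [min_heavy_distance()]) is within 0.5 angstrom of its target;
#' infeasible constraint sets raise an error naming the violated pair.
#' Deterministic per seed.
#'
#' @param spec an [fv_spec()].
#' @param id structure id.
#' @return list with `structure` (an [fv_structure()] that passes
#'   [filter_crystal_set()] under its default metadata) and `truth`
#'   (realized minimum distances for all 15 CDR pairs, loop lengths, seed).
#' @export
make_fv <- function(spec = fv_spec(), id = "synthetic_fv") {
  with_seed(spec$seed, {
    tabs <- list()
    loop_row_idx <- list()
    n_so_far <- 0L
    for (ch in c("H", "L")) {
      cdr_pos <- list(CDR1 = imgt_positions_for_length("CDR1", spec$loop_lengths[paste0(ch, "1")]),
                      CDR2 = imgt_positions_for_length("CDR2", spec$loop_lengths[paste0(ch, "2")]),
                      CDR3 = imgt_positions_for_length("CDR3", spec$loop_lengths[paste0(ch, "3")]))
      all_cdr <- unlist(lapply(.CDR_RANGES, function(r) r[1]:r[2]))
      fw_pos <- setdiff(.IMGT_MIN:.IMGT_MAX, all_cdr)
      # framework path: zigzag line behind the loops
      k <- seq_along(fw_pos)
      y_fw <- if (ch == "H") 24 else -24
      fw_centers <- cbind(-70 + 1.5 * k,
                          y_fw + 0.6 * sin(1.7 * k),
                          -6 + 0.8 * cos(1.1 * k))
      # the 5 framework residues flanking each CDR sit next to the loop
      # base (as in a real chain), so flank/anchor superposition has no
      # long lever arm to the framework line
      for (reg in names(cdr_pos)) {
        lab <- region_label(ch, reg)
        ctr <- .LOOP_CENTERS[lab, ]
        L <- length(cdr_pos[[reg]])
        rho <- if (L == 1) 2 else max(2, 3.8 * (L - 1) / pi)
        rng <- .CDR_RANGES[[reg]]
        for (j in 1:5) {
          i_before <- match(rng[1] - j, fw_pos)
          if (!is.na(i_before))
            fw_centers[i_before, ] <- c(ctr[1] - rho - 2.0 * j,
                                        ctr[2] + 0.4 * sin(j),
                                        ctr[3] - 1.5 - 0.5 * j)
          i_after <- match(rng[2] + j, fw_pos)
          if (!is.na(i_after))
            fw_centers[i_after, ] <- c(ctr[1] + rho + 2.0 * j,
                                       ctr[2] - 0.4 * sin(j),
                                       ctr[3] - 1.5 - 0.5 * j)
        }
      }
      fw_aa <- sample(.AA20, length(fw_pos), replace = TRUE)
      tabs[[length(tabs) + 1]] <- .residues_atoms(ch, fw_pos, 0L, fw_aa,
                                                  fw_centers)
      n_so_far <- n_so_far + nrow(tabs[[length(tabs)]])
      for (reg in names(cdr_pos)) {
        pos <- cdr_pos[[reg]]
        lab <- region_label(ch, reg)
        centers <- .arc_centers(length(pos), .LOOP_CENTERS[lab, ])
        aa <- sample(.AA20, length(pos), replace = TRUE)
        tab <- .residues_atoms(ch, pos, 0L, aa, centers)
        tabs[[length(tabs) + 1]] <- tab
        loop_row_idx[[lab]] <- n_so_far + seq_len(nrow(tab))
        n_so_far <- n_so_far + nrow(tab)
      }
    }
    atoms <- do.call(rbind, tabs)
    jit <- matrix(stats::rnorm(3 * nrow(atoms), sd = 0.03), ncol = 3)
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] + jit

    # realize requested minimum-distance targets by translating loops
    # along the line between loop centroids
    gaps <- spec$inter_loop_gap
    if (length(gaps)) {
      parse_pair <- function(nm) strsplit(nm, "|", fixed = TRUE)[[1]]
      for (it in seq_len(40)) {
        worst <- 0
        for (nm in names(gaps)) {
          pr <- parse_pair(nm)
          if (!all(pr %in% names(loop_row_idx)))
            stop("unknown loop pair in gap spec: ", nm, call. = FALSE)
          ca <- as.matrix(atoms[loop_row_idx[[pr[1]]], c("x", "y", "z")])
          cb <- as.matrix(atoms[loop_row_idx[[pr[2]]], c("x", "y", "z")])
          d <- min_heavy_distance(ca, cb)
          err <- d - gaps[[nm]]
          worst <- max(worst, abs(err))
          if (abs(err) > 0.05) {
            dir <- colMeans(cb) - colMeans(ca)
            dir <- dir / sqrt(sum(dir^2))
            idx <- loop_row_idx[[pr[2]]]
            shift <- matrix(err * dir, nrow = length(idx), ncol = 3,
                            byrow = TRUE)
            atoms[idx, c("x", "y", "z")] <-
              as.matrix(atoms[idx, c("x", "y", "z")]) - shift
          }
        }
        if (worst <= 0.05) break
      }
      for (nm in names(gaps)) {
        pr <- parse_pair(nm)
        ca <- as.matrix(atoms[loop_row_idx[[pr[1]]], c("x", "y", "z")])
        cb <- as.matrix(atoms[loop_row_idx[[pr[2]]], c("x", "y", "z")])
        if (abs(min_heavy_distance(ca, cb) - gaps[[nm]]) > 0.5)
          stop("infeasible inter-loop gap constraint for pair ", nm,
               call. = FALSE)
      }
    }

    md <- utils::modifyList(
      list(method = "X-RAY DIFFRACTION", resolution = 2.0, subtype = "kappa",
           vh_gene = "IGHV3", vl_gene = "IGKV1",
           canonical_forms = list(h1 = paste0("H1-", spec$loop_lengths["H1"], "-A"),
                                  h2 = paste0("H2-", spec$loop_lengths["H2"], "-A"),
                                  l1 = paste0("L1-", spec$loop_lengths["L1"], "-A"),
                                  l2 = paste0("L2-", spec$loop_lengths["L2"], "-A"),
                                  l3 = paste0("L3-", spec$loop_lengths["L3"], "-A"))),
      spec$metadata)
    fv <- fv_structure(id, atoms, md)
    labs <- cdr_labels()
    pairs <- utils::combn(labs, 2, simplify = FALSE)
    realized <- vapply(pairs, function(p)
      min_heavy_distance(select_loop(fv, p[1], "heavy"),
                         select_loop(fv, p[2], "heavy")), numeric(1))
    names(realized) <- vapply(pairs, paste, character(1), collapse = "|")
    list(structure = fv,
         truth = list(realized_gaps = realized,
                      loop_lengths = spec$loop_lengths, seed = spec$seed))
  })
}

#' Specification for a synthetic biased ensemble
#'
#' @param n_frames number of frames.
#' @param n_states number of discrete CDR-H3 conformational states (1-4).
#' @param state_separation target loop-backbone RMSD between state
#'   templates in angstrom.
#' @param jitter per-frame Gaussian positional noise, expressed as the
#'   approximate RMSD (angstrom) it adds to a frame.
#' @param bias_strength free-energy spacing between consecutive states in
#'   kJ/mol; unbiased state populations are Boltzmann in these energies.
#' @param temperature kelvin.
#' @param seed integer seed.
#' @param loops loops switched between states (default CDR-H3; CDR-L3 may
#'   be added).
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_frames = 500, n_states = 2, state_separation = 3,
                          jitter = 0.3, bias_strength = 3, temperature = 300,
                          seed = 1, loops = "CDR-H3") {
  if (n_states < 1 || n_states > 4)
    stop("n_states must be between 1 and 4", call. = FALSE)
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  structure(list(n_frames = as.integer(n_frames), n_states = as.integer(n_states),
                 state_separation = state_separation, jitter = jitter,
                 bias_strength = bias_strength, temperature = temperature,
                 seed = as.integer(seed), loops = loops),
            class = "ensemble_spec")
}

# unit displacement vertices with equal pairwise separation, K <= 4
.state_dirs <- function(K) {
  v <- switch(K,
              matrix(0, 1, 3),
              rbind(c(0, 0, 0), c(0, 0, 1)),
              rbind(c(0, 0, 0), c(0, 0, 1), c(0, sqrt(3) / 2, 0.5)),
              rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
                sqrt(3) / (2 * sqrt(2) / sqrt(3)))
  sweep(v, 2, v[1, ])    # state 1 at the origin (the reference conformation)
}

#' Generate a synthetic biased ensemble
#'
#' Frames switch the chosen loop(s) between `n_states` template
#' conformations (rigid loop translations along equal-separation
#' directions, so the loop-backbone RMSD between templates equals
#' `state_separation` exactly) with Gaussian jitter on every atom. States
#' are sampled uniformly — the flat landscape of a converged metadynamics
#' run — and each frame carries the deposited bias
#' `V_k = max(F) - F_k` for state free energies
#' `F_k = (k - 1) * bias_strength`, so that reweighting
#' (`w proportional to exp(V / kB T)`) must recover the Boltzmann
#' populations `p_k proportional to exp(-F_k / kB T)`. Frame 1 is forced
#' to state 1 (the "crystal" reference conformation). A warning is issued
#' when `state_separation < 3 * jitter` (states not separable at the
#' clustering cutoff).
#'
#' @param base an [fv_structure()] (or the list from [make_fv()]).
#' @param spec an [ensemble_spec()].
#' @return list with `ensemble` (an [fv_ensemble()]) and `truth` (state
#'   labels, true Boltzmann populations, per-state bias, displacement
#'   directions).
#' @export
make_ensemble <- function(base, spec = ensemble_spec()) {
  if (!inherits(base, "fv_structure")) base <- base$structure
  if (spec$state_separation < 3 * spec$jitter && spec$n_states > 1)
    warning("state separation below 3x jitter: states may not be separable",
            call. = FALSE)
  with_seed(spec$seed, {
    coords <- as.matrix(base$atoms[, c("x", "y", "z")])
    A <- nrow(coords); nfr <- spec$n_frames; K <- spec$n_states
    loop_rows <- unlist(lapply(spec$loops, function(l) {
      pl <- parse_region_label(l)
      which(base$atoms$chain == pl$chain &
              assign_region(base$atoms$imgt_number, pl$chain) == l)
    }))
    dirs <- .state_dirs(K) * spec$state_separation
    Fk <- (seq_len(K) - 1) * spec$bias_strength
    Vk <- max(Fk) - Fk
    p_true <- exp(-Fk / (.kB * spec$temperature))
    p_true <- p_true / sum(p_true)
    states <- sample.int(K, nfr, replace = TRUE)
    states[1] <- 1L
    sigma <- spec$jitter / sqrt(3)
    xyz <- matrix(0, nfr, 3 * A)
    for (f in seq_len(nfr)) {
      fc <- coords
      fc[loop_rows, ] <- fc[loop_rows, ] +
        matrix(dirs[states[f], ], length(loop_rows), 3, byrow = TRUE)
      if (sigma > 0) fc <- fc + matrix(stats::rnorm(3 * A, sd = sigma), A, 3)
      xyz[f, ] <- as.vector(t(fc))
    }
    map <- base$atoms[, c("chain", "imgt_number", "imgt_insertion", "aa",
                          "atom", "element")]
    ens <- fv_ensemble(xyz, map, bias = Vk[states],
                       temperature = spec$temperature)
    list(ensemble = ens,
         truth = list(states = states, p_true = p_true, bias_by_state = Vk,
                      dirs = dirs, seed = spec$seed))
  })
}

#' Generate a loop population with planted per-stratum diversity offsets
#'
#' Builds `sum(n_per_stratum)` equal-length CDR-H3 loops sharing one fixed
#' anchor set: each loop is a common base arc plus an independent Gaussian
#' backbone perturbation whose scale is stratum-specific. Because anchors
#' are identical, the DTW distance between two loops is exactly their
#' backbone RMSD, which lets the generator calibrate scales by direct
#' evaluation of the full distance matrix: a global scale sets the
#' baseline mean DTW near `baseline_target`, and per-stratum scales are
#' iterated until every realized percent delta (stratum mean vs baseline)
#' is within 1 percentage point of its planted value; an unreachable
#' planting raises an error.
#'
#' @param n_per_stratum named integer vector (stratum label -> size).
#' @param delta_pct named numeric vector of planted percent deltas over a
#'   subset of the strata; untargeted strata act as background and absorb
#'   the pair-sum constraint (within- plus cross-stratum pair means must
#'   average to the baseline, so planting every stratum simultaneously is
#'   in general over-constrained). `NULL` plants nothing (all strata drawn
#'   from one spread).
#' @param seed integer seed.
#' @param baseline_target target baseline mean DTW distance in angstrom.
#' @param loop_length residues per loop.
#' @return list with `loops` (list of [anchored_loop()]), `matrix` (the DTW
#'   distance matrix from [pairwise_dtw()]), `stratification` (data.frame
#'   `id`, `stratum`) and `truth` (planted and realized deltas, scales,
#'   baseline).
#' @export
make_loop_population <- function(n_per_stratum, delta_pct = NULL, seed = 1,
                                 baseline_target = 1.5, loop_length = 13L) {
  strata <- names(n_per_stratum)
  if (is.null(strata)) stop("n_per_stratum must be named", call. = FALSE)
  if (is.null(delta_pct)) delta_pct <- stats::setNames(numeric(0), character(0))
  if (!all(names(delta_pct) %in% strata))
    stop("delta_pct names must be strata", call. = FALSE)
  targeted <- names(delta_pct)
  with_seed(seed, {
    n <- sum(n_per_stratum)
    member_stratum <- rep(strata, n_per_stratum)
    ids <- paste0(member_stratum, "_",
                  unlist(lapply(n_per_stratum, seq_len)))
    L <- as.integer(loop_length)
    base_centers <- .arc_centers(L, c(0, 0, 0))
    base_bb <- .residues_atoms("H", seq_len(L), 0L, "A", base_centers,
                               atoms = .BACKBONE)
    base_flat <- as.vector(as.matrix(base_bb[, c("x", "y", "z")]))
    anc_centers <- rbind(cbind(seq(-14, by = 2.2, length.out = 5), 0.5, -3),
                         cbind(seq(6, by = 2.2, length.out = 5), -0.5, -3))
    anc_bb <- .residues_atoms("H", c(100:104, 118:122), 0L, "A", anc_centers,
                              atoms = .BACKBONE)
    anchor <- as.matrix(anc_bb[, c("x", "y", "z")])
    eps <- matrix(stats::rnorm(n * 4 * L * 3), n)   # unit perturbations

    scales <- stats::setNames(rep(1, length(strata)), strata)
    dist_from_scales <- function(sc) {
      flat <- eps * sc[member_stratum]
      as.matrix(stats::dist(flat)) / sqrt(4 * L)
    }
    realized <- NULL
    for (it in seq_len(12)) {
      D <- dist_from_scales(scales)
      base_mean <- sum(D) / (n * (n - 1))
      scales <- scales * baseline_target / base_mean
      D <- D * baseline_target / base_mean
      base_mean <- baseline_target
      realized <- vapply(strata, function(s) {
        idx <- which(member_stratum == s)
        if (length(idx) < 2) return(NA_real_)
        100 * (sum(D[idx, idx]) / (length(idx) * (length(idx) - 1)) -
                 base_mean) / base_mean
      }, numeric(1))
      if (!length(targeted)) break
      err <- realized[targeted] - delta_pct[targeted]
      if (all(abs(err[!is.na(err)]) <= 0.25)) break
      adj <- (1 + delta_pct[targeted] / 100) / (1 + realized[targeted] / 100)
      adj[is.na(adj) | adj <= 0] <- 1
      scales[targeted] <- scales[targeted] * adj
    }
    if (length(targeted) &&
        any(abs((realized[targeted] - delta_pct[targeted])[
          !is.na(realized[targeted])]) > 1))
      stop("planted stratum delta unreachable at the given sizes ",
           "(worst stratum: ",
           targeted[which.max(abs(realized[targeted] - delta_pct[targeted]))],
           ")", call. = FALSE)

    loops <- lapply(seq_len(n), function(i) {
      lb <- matrix(base_flat + eps[i, ] * scales[member_stratum[i]],
                   ncol = 3)
      anchored_loop(lb, anchor, id = ids[i])
    })
    names(loops) <- ids
    D <- pairwise_dtw(loops)
    list(loops = loops, matrix = D,
         stratification = data.frame(id = ids, stratum = member_stratum,
                                     stringsAsFactors = FALSE),
         truth = list(planted_delta_pct = delta_pct,
                      realized_delta_pct = realized,
                      scales = scales, baseline = baseline_target,
                      seed = seed))
  })
}

#' Specification for a synthetic pairing cohort
#'
#' @param n_families number of identical-VH families.
#' @param copies_per_family structures per family (default 2; with more
#'   than 2, members carry disjoint VL mutation sets so all pairwise
#'   identities stay exact, but the planted correlation is only
#'   guaranteed for 2-copy families).
#' @param vl_divergence target VL identities as fractions (recycled across
#'   families); default: drawn uniformly from [0.45, 0.985].
#' @param planted_r target Pearson correlation between VL identity and
#'   CDR-H3 displacement across qualifying pairs.
#' @param forms_change_probability probability that a pair differs in at
#'   least one VL canonical form.
#' @param effect `"identity"` (default: displacement drawn to correlate
#'   with VL identity at `planted_r`; form flips independent) or `"forms"`
#'   (displacement depends only on the form flip, whose probability falls
#'   with VL identity — the correlation is routed solely through canonical
#'   forms, so it must vanish within the forms-equal subgroup).
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_families = 86, copies_per_family = 2,
                        vl_divergence = NULL, planted_r = -0.49,
                        forms_change_probability = 0.3,
                        effect = c("identity", "forms"), seed = 1) {
  effect <- match.arg(effect)
  if (abs(planted_r) > 1) stop("planted_r must be in [-1, 1]", call. = FALSE)
  structure(list(n_families = as.integer(n_families),
                 copies_per_family = as.integer(copies_per_family),
                 vl_divergence = vl_divergence, planted_r = planted_r,
                 forms_change_probability = forms_change_probability,
                 effect = effect, seed = as.integer(seed)),
            class = "cohort_spec")
}

.rand_seq <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")

# substitute k positions of a sequence with different residues
.mutate_seq <- function(s, positions) {
  v <- strsplit(s, "")[[1]]
  for (p in positions) {
    v[p] <- sample(setdiff(.AA20, v[p]), 1)
  }
  paste(v, collapse = "")
}

#' Generate a synthetic identical-VH / divergent-VL cohort
#'
#' Families share one VH sequence (distinct across families); within each
#' family, members carry VL sequences mutated from a family base by
#' substitutions only (no indels) at disjoint position sets, and the
#' resulting pairwise VL identities are measured with [global_identity()]
#' so the ground truth is exactly what the analysis will see. All members share one Fv
#' geometry except the CDR-H3 loop, which is rigidly displaced per member:
#' because the framework is identical, the realized pair CDR-H3 backbone
#' RMSD after VH-framework alignment equals the planted displacement
#' exactly, while CDR-H1/CDR-H2/FW-H RMSDs are zero. Displacements are
#' drawn so that the correlation between VL identity and CDR-H3 RMSD over
#' qualifying pairs equals `planted_r` in expectation (`effect =
#' "identity"`), or so that the effect is routed solely through canonical-
#' form changes (`effect = "forms"`). A small independent positional
#' jitter (0.05 angstrom per coordinate) keeps framework and minor-loop
#' RMSDs non-degenerate.
#'
#' @param spec a [cohort_spec()].
#' @return list with `records` (list of [sequence_record()]), `truth`
#'   (data.frame `id_a`, `id_b`, `vl_identity`, `rmsd_h3`, `forms_equal`
#'   over the planted qualifying pairs, plus `planted_r`), and `base` (the
#'   shared [fv_structure()]).
#' @export
make_pairing_cohort <- function(spec = cohort_spec()) {
  with_seed(spec$seed, {
    base <- make_fv(fv_spec(seed = spec$seed + 1000L), id = "cohort_base")$structure
    h3_rows <- which(base$atoms$chain == "H" &
                       assign_region(base$atoms$imgt_number, "H") == "CDR-H3")
    vl_len <- 110L
    nf <- spec$n_families
    m <- spec$copies_per_family
    if (m < 2) stop("copies_per_family must be >= 2", call. = FALSE)
    div <- spec$vl_divergence
    if (is.null(div)) div <- stats::runif(nf, 0.45, 0.985)
    div <- rep(div, length.out = nf)
    k_mut <- round((1 - div) * vl_len)

    # sequences first: mutations are substitutions at disjoint position
    # sets, and the planted identity of each pair is then *measured* with
    # the package's own alignment (at low identity the gapped global
    # alignment can recover slightly more matches than the substitution
    # diagonal, and the ground truth must be what the analysis will see)
    vh_seqs <- vapply(seq_len(nf), function(f) .rand_seq(120L), character(1))
    vl_seqs <- vector("list", nf)
    for (f in seq_len(nf)) {
      vl_base <- .rand_seq(vl_len)
      sizes <- c(0L, rep(k_mut[f], m - 1))
      if (sum(sizes) > vl_len)
        stop("family ", f, ": mutation sets exceed the VL length",
             call. = FALSE)
      avail <- sample.int(vl_len)
      ofs <- 0L
      vl_seqs[[f]] <- vapply(seq_len(m), function(j) {
        pos <- if (sizes[j] > 0) avail[(ofs + 1):(ofs + sizes[j])] else integer(0)
        ofs <<- ofs + sizes[j]
        if (length(pos)) .mutate_seq(vl_base, pos) else vl_base
      }, character(1))
    }
    # measured identity of the family's lead pair drives the plant
    identity <- vapply(seq_len(nf), function(f)
      global_identity(vl_seqs[[f]][1], vl_seqs[[f]][2]), numeric(1))

    # displacement magnitudes and form flips, pair-level (2-copy families)
    if (spec$effect == "identity") {
      xs <- as.vector(scale(identity))
      if (any(!is.finite(xs))) xs <- rep(0, nf)
      ys <- spec$planted_r * xs +
        sqrt(max(0, 1 - spec$planted_r^2)) * stats::rnorm(nf)
      disp <- pmax(0.15, 2.5 + 0.7 * ys)
      flip <- stats::runif(nf) < spec$forms_change_probability
    } else {
      p_flip <- pmin(0.9, pmax(0.05, 0.8 * (1 - identity / 100)))
      flip <- stats::runif(nf) < p_flip
      disp <- pmax(0.1, 2.0 + 0.3 * stats::rnorm(nf) + 1.8 * flip)
    }

    base_forms <- list(l1 = "L1-7-A", l2 = "L2-3-A", l3 = "L3-9-A")
    records <- list()
    truth_rows <- list()
    for (f in seq_len(nf)) {
      fam <- sprintf("fam%03d", f)
      for (j in seq_len(m)) {
        flip_j <- j > 1 && flip[f]
        forms_j <- base_forms
        if (flip_j) forms_j$l3 <- "L3-10-A"
        disp_j <- if (j == 1) 0 else disp[f] * (j - 1)
        st <- base
        st$id <- paste0(fam, "_", letters[j])
        st$atoms[h3_rows, "z"] <- st$atoms[h3_rows, "z"] + disp_j
        # small independent positional noise so framework and minor-loop
        # RMSDs are realistically non-zero (the planted H3 displacement
        # dominates the pair CDR-H3 RMSD up to this jitter)
        st$atoms[, c("x", "y", "z")] <- st$atoms[, c("x", "y", "z")] +
          matrix(stats::rnorm(3 * nrow(st$atoms), sd = 0.05), ncol = 3)
        records[[length(records) + 1]] <-
          sequence_record(st$id, vh_seqs[f], vl_seqs[[f]][j],
                          structure = st, vl_forms = forms_j)
      }
      for (j in seq_len(m - 1)) {
        for (jj in (j + 1):m) {
          pid <- if (j == 1 && jj == 2) identity[f] else
            global_identity(vl_seqs[[f]][j], vl_seqs[[f]][jj])
          if (pid < 99 && pid >= 40) {
            truth_rows[[length(truth_rows) + 1]] <- data.frame(
              id_a = paste0(fam, "_", letters[j]),
              id_b = paste0(fam, "_", letters[jj]),
              vl_identity = pid,
              rmsd_h3 = abs(jj - j) * disp[f],
              forms_equal = if (j == 1) !flip[f] else TRUE,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    truth <- do.call(rbind, truth_rows)
    truth <- truth[order(truth$id_a, truth$id_b), , drop = FALSE]
    rownames(truth) <- NULL
    list(records = records,
         truth = list(pairs = truth, planted_r = spec$planted_r,
                      seed = spec$seed),
         base = base)
  })
}
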