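# Generator self-consistency: every planted quantity is re-measured with
# the analysis modules.

test_that("the Fv generator is deterministic and covers all six loops", {
  r1 <- make_fv(fv_spec(seed = 601))
  r2 <- make_fv(fv_spec(seed = 601))
  expect_identical(r1$structure$atoms, r2$structure$atoms)
  r3 <- make_fv(fv_spec(seed = 602))
  expect_false(identical(r1$structure$atoms, r3$structure$atoms))
  fv <- r1$structure
  for (lab in cdr_labels()) {
    sel <- select_loop(fv, lab, "heavy")
    pl <- parse_region_label(lab)
    len <- fv_spec()$loop_lengths[paste0(pl$chain, substr(pl$region, 4, 4))]
    expect_equal(length(unique(paste(sel$atoms$imgt_number,
                                     sel$atoms$imgt_insertion))),
                 unname(len))
  }
  # default output passes the crystal-set filter with zero rejections
  res <- filter_crystal_set(list(fv))
  expect_length(res$kept, 1L)
  expect_equal(nrow(res$log), 0L)
  # anchors and flanks exist: the loop is DTW- and series-eligible
  expect_false(is.null(anchored_loop_from_fv(fv)))
})

test_that("requested inter-loop gaps are realized within tolerance", {
  for (g in c(3.5, 4.0, 6.0)) {
    r <- make_fv(fv_spec(inter_loop_gap = list("CDR-H3|CDR-L3" = g),
                         seed = 603))
    realized <- r$truth$realized_gaps["CDR-H3|CDR-L3"]
    expect_lt(abs(realized - g), 0.5)
    d <- min_heavy_distance(select_loop(r$structure, "CDR-H3", "heavy"),
                            select_loop(r$structure, "CDR-L3", "heavy"))
    expect_equal(unname(realized), d, tolerance = 1e-12)
  }
  expect_error(make_fv(fv_spec(inter_loop_gap = list("CDR-H3|CDR-X1" = 3))),
               "unknown loop pair")
})

test_that("ensemble generation plants states, bias and populations coherently", {
  base <- make_fv(fv_spec(seed = 604))$structure
  # single state: the loop only jitters, native throughout
  e1 <- make_ensemble(base, ensemble_spec(n_frames = 60, n_states = 1,
                                          jitter = 0.2, seed = 1))
  ser <- loop_rmsd_series(e1$ensemble, "CDR-H3")
  expect_lt(rmsf(ser), 1)
  expect_gte(native_fraction(ser), 0.95)
  # zero free-energy spacing: bias is flat, weights reduce to frequencies
  e0 <- make_ensemble(base, ensemble_spec(n_frames = 200, n_states = 2,
                                          bias_strength = 0, seed = 2))
  w <- reweight(e0$ensemble)
  expect_equal(as.numeric(w), rep(1 / 200, 200))
  expect_equal(e0$truth$p_true, c(0.5, 0.5))
  # biased two-state ensemble: reweighted populations approach the truth
  e2 <- make_ensemble(base, ensemble_spec(n_frames = 400, n_states = 2,
                                          bias_strength = 3, seed = 3))
  w2 <- as.numeric(reweight(e2$ensemble))
  pop1 <- sum(w2[e2$truth$states == 1])
  expect_lt(abs(pop1 - e2$truth$p_true[1]), 0.05)
  # separable states are recovered by clustering with matching labels
  cl <- cluster_frames(e2$ensemble)
  expect_equal(length(cl$representatives), 2L)
  expect_gte(label_agreement(cl$labels, e2$truth$states), 0.99)
  expect_warning(make_ensemble(base, ensemble_spec(state_separation = 0.5,
                                                   jitter = 0.3, seed = 1,
                                                   n_frames = 5)),
                 "separable")
})

test_that("loop populations realize planted diversity deltas", {
  pop <- make_loop_population(c(hit = 40, bg = 120), c(hit = -10),
                              seed = 605, baseline_target = 1.5)
  expect_lt(abs(pop$truth$realized_delta_pct["hit"] + 10), 1)
  expect_equal(mean_intra_distance(pop$matrix), 1.5, tolerance = 1e-6)
  dr <- diversity_report(pop$matrix, pop$stratification, n_boot = 1000,
                         seed = 1)
  hit <- dr[dr$stratum == "hit", ]
  expect_lt(hit$delta_pct, -7)
  expect_gt(hit$delta_pct, -13)
  expect_lt(hit$p_value, 0.05)
  # opposite planted signs come out with opposite signs
  pop2 <- make_loop_population(c(a = 30, b = 30, bg = 60),
                               c(a = 5, b = -5), seed = 606)
  expect_gt(pop2$truth$realized_delta_pct["a"], 0)
  expect_lt(pop2$truth$realized_delta_pct["b"], 0)
  # null planting: report deltas hover near zero
  pop0 <- make_loop_population(c(a = 40, b = 40), seed = 607)
  dr0 <- diversity_report(pop0$matrix, pop0$stratification, n_boot = 500,
                          seed = 2)
  expect_lt(max(abs(dr0$delta_pct)), 3)
  # determinism
  popA <- make_loop_population(c(a = 10, b = 10), c(a = -5), seed = 608)
  popB <- make_loop_population(c(a = 10, b = 10), c(a = -5), seed = 608)
  expect_identical(popA$matrix, popB$matrix)
})

test_that("pairing cohorts plant recoverable pairs and correlations", {
  co <- make_pairing_cohort(cohort_spec(n_families = 25, seed = 609))
  pairs <- extract_pairs(co$records)
  expect_equal(pairs[, c("id_a", "id_b")],
               co$truth$pairs[, c("id_a", "id_b")])
  expect_equal(pairs$vl_identity, co$truth$pairs$vl_identity,
               tolerance = 1e-9)
  pa <- pairing_analysis(co$records, pairs = pairs)
  expect_equal(pa$pairs$rmsd_h3, co$truth$pairs$rmsd_h3, tolerance = 0.1)
  expect_equal(pa$pairs$forms_equal, co$truth$pairs$forms_equal)
  # a null cohort leaves no correlation to find
  co0 <- make_pairing_cohort(cohort_spec(n_families = 60, planted_r = 0,
                                         seed = 610))
  pa0 <- pairing_analysis(co0$records)
  r0 <- pa0$correlations$r[pa0$correlations$region == "CDR-H3"]
  expect_lt(abs(r0), 0.3)
})
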