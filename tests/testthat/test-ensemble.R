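# Ensemble post-processing: reweighting, RMSD series, RMSF, native
# fractions, frame clustering.

kB <- 0.008314462618

test_that("reweighting follows the closed form and its invariances", {
  w0 <- reweight(rep(0, 10), temperature = 300)
  expect_equal(as.numeric(w0), rep(0.1, 10))
  # two frames with V = (0, kB*T*ln 2) -> weights (1/3, 2/3)
  w <- reweight(c(0, kB * 300 * log(2)), temperature = 300)
  expect_equal(as.numeric(w), c(1 / 3, 2 / 3), tolerance = 1e-12)
  # shift invariance and normalization
  set.seed(401)
  v <- rnorm(50, sd = 10)
  expect_equal(as.numeric(reweight(v, 300)),
               as.numeric(reweight(v + 123.4, 300)), tolerance = 1e-12)
  expect_equal(sum(reweight(v, 300)), 1, tolerance = 1e-12)
  expect_error(reweight(c(1, NA), 300), "finite")
  expect_error(reweight(c(1, 2), -5), "positive")
})

test_that("loop RMSD series removes rigid motion and reads displacements", {
  base <- make_fv(fv_spec(seed = 402))$structure
  coords <- as.matrix(base$atoms[, c("x", "y", "z")])
  h3 <- which(base$atoms$chain == "H" &
                assign_region(base$atoms$imgt_number, "H") == "CDR-H3")
  d <- 2.5
  disp <- coords; disp[h3, 3] <- disp[h3, 3] + d
  rigid <- rand_rigid(coords)
  xyz <- rbind(as.vector(t(coords)), as.vector(t(disp)), as.vector(t(rigid)))
  ens <- fv_ensemble(xyz, base$atoms[, c("chain", "imgt_number",
                                         "imgt_insertion", "aa", "atom",
                                         "element")])
  ser <- loop_rmsd_series(ens, "CDR-H3")
  expect_equal(ser[1], 0, tolerance = 1e-10)
  expect_equal(ser[2], d, tolerance = 1e-6)   # flanks fixed, pure loop shift
  expect_lt(ser[3], 1e-7)                      # alignment removes rigid motion
  expect_error(loop_rmsd_series(ens, "CDR-H1", anchor_width = 50), "flank")
})

test_that("rmsf and native fraction are weighted series summaries", {
  expect_equal(rmsf(rep(0, 5)), 0)
  set.seed(403)
  ser <- abs(rnorm(100)); w <- as.numeric(reweight(rnorm(100), 300))
  expect_equal(rmsf(ser), mean(ser), tolerance = 1e-12)
  expect_equal(rmsf(ser, w), sum(w * ser), tolerance = 1e-12)
  expect_equal(native_fraction(rep(0, 7)), 1.0)
  # half the weight mass below the cutoff by construction
  s2 <- c(0.5, 0.5, 2, 2)
  expect_equal(native_fraction(s2, c(0.25, 0.25, 0.25, 0.25)), 0.5)
  expect_equal(native_fraction(c(0.9, 1.0, 1.1), cutoff = 1.0), 2 / 3)
  expect_error(rmsf(1:3, c(0.5, 0.5)), "length")
})

test_that("frame clustering handles degenerate inputs and the cutoff", {
  base <- make_fv(fv_spec(seed = 404))$structure
  e1 <- make_ensemble(base, ensemble_spec(n_frames = 1, n_states = 1,
                                          jitter = 0, seed = 1))
  cl1 <- cluster_frames(e1$ensemble)
  expect_equal(cl1$labels, 1L)
  expect_equal(cl1$representatives, 1L)
  e <- make_ensemble(base, ensemble_spec(n_frames = 40, n_states = 2,
                                         state_separation = 3, jitter = 0.3,
                                         seed = 2))
  # cutoff above the maximum pairwise distance -> one cluster
  clbig <- cluster_frames(e$ensemble, cutoff = 1e4)
  expect_equal(length(clbig$representatives), 1L)
  # cluster count is non-increasing in the cutoff
  cuts <- c(0.3, 0.8, 1.25, 2.5, 6)
  ks <- vapply(cuts, function(h)
    length(cluster_frames(e$ensemble, cutoff = h)$representatives),
    integer(1))
  expect_true(all(diff(ks) <= 0))
  # representatives belong to their clusters
  cl <- cluster_frames(e$ensemble)
  expect_true(all(cl$labels[cl$representatives] == seq_along(cl$representatives)))
})

test_that("average-linkage merge heights match the naive oracle", {
  base <- make_fv(fv_spec(seed = 405))$structure
  e <- make_ensemble(base, ensemble_spec(n_frames = 15, n_states = 3,
                                         state_separation = 3, jitter = 0.4,
                                         seed = 3))
  cl <- cluster_frames(e$ensemble)
  expect_equal(sort(cl$hclust$height),
               sort(oracle_avg_linkage_heights(as.matrix(cl$dist))),
               tolerance = 1e-9)
})
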