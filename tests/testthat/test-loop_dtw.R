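# Anchor-superposed dynamic time warping of CDR-H3 loops.

test_that("anchor superposition inverts rigid motions and improves fit", {
  set.seed(201)
  a <- rand_anchored_loop(10)
  same <- anchor_superpose(a, a)
  expect_equal(same$loop_bb, a$loop_bb, tolerance = 1e-10)
  moved <- move_anchored_loop(a)
  back <- anchor_superpose(moved, a)
  expect_equal(back$loop_bb, a$loop_bb, tolerance = 1e-8)
  for (k in 1:20) {
    x <- rand_anchored_loop(8)
    y <- rand_anchored_loop(8)
    before <- rmsd_coords(x$anchor_bb, y$anchor_bb)
    after <- rmsd_coords(anchor_superpose(x, y)$anchor_bb, y$anchor_bb)
    expect_lte(after, before + 1e-9)
  }
})

test_that("identical loops give zero distance and a diagonal path", {
  a <- rand_anchored_loop(12)
  res <- dtw_distance(a, a)
  expect_lt(res$distance, 1e-9)
  expect_equal(res$path, cbind(1:12, 1:12), ignore_attr = TRUE)
  moved <- move_anchored_loop(a)
  expect_lt(dtw_distance(moved, a)$distance, 1e-8)
})

test_that("equal-length comparison is exactly anchored backbone RMSD", {
  set.seed(202)
  for (k in 1:25) {
    L <- sample(5:15, 1)
    a <- rand_anchored_loop(L); b <- rand_anchored_loop(L)
    expected <- rmsd_coords(anchor_superpose(a, b)$loop_bb, b$loop_bb)
    expect_equal(dtw_distance(a, b)$distance, expected, tolerance = 1e-12)
  }
})

test_that("the dynamic program equals exhaustive path enumeration", {
  set.seed(203)
  for (k in 1:40) {
    la <- sample(3:6, 1); lb <- sample(3:6, 1)
    if (la == lb) lb <- lb + 1
    a <- rand_anchored_loop(la); b <- rand_anchored_loop(lb)
    asup <- anchor_superpose(a, b)
    cost <- oracle_cost_matrix(asup$loop_bb, b$loop_bb)
    res <- dtw_distance(a, b)
    total <- res$distance^2 * 4 * nrow(res$path)
    expect_equal(total, oracle_dtw_total_cost(cost), tolerance = 1e-8)
    # the reported path realizes the reported cost
    expect_equal(sum(cost[res$path]), total, tolerance = 1e-8)
  }
})

test_that("dtw distance is symmetric and scales linearly with deviations", {
  set.seed(204)
  for (k in 1:15) {
    a <- rand_anchored_loop(sample(4:9, 1))
    b <- rand_anchored_loop(sample(4:9, 1))
    expect_equal(dtw_distance(a, b)$distance, dtw_distance(b, a)$distance,
                 tolerance = 1e-9)
    # scaling both structures about the origin scales every deviation by s
    s <- runif(1, 1, 3)
    as_ <- anchored_loop(a$loop_bb * s, a$anchor_bb * s)
    bs_ <- anchored_loop(b$loop_bb * s, b$anchor_bb * s)
    expect_equal(dtw_distance(as_, bs_)$distance,
                 s * dtw_distance(a, b)$distance, tolerance = 1e-9)
  }
})

test_that("the pairwise matrix is symmetric, zero-diagonal and consistent", {
  set.seed(205)
  loops <- lapply(1:8, function(i)
    rand_anchored_loop(sample(5:9, 1), id = paste0("l", i)))
  D <- pairwise_dtw(loops)
  expect_equal(diag(D), rep(0, 8), ignore_attr = TRUE)
  expect_equal(unclass(D), t(unclass(D)), tolerance = 1e-12)
  for (k in 1:10) {
    ij <- sort(sample(8, 2))
    expect_equal(D[ij[1], ij[2]],
                 dtw_distance(loops[[ij[1]]], loops[[ij[2]]])$distance,
                 tolerance = 1e-12)
  }
  # n identical loops -> zero matrix
  same <- lapply(1:4, function(i) loops[[1]])
  expect_true(all(pairwise_dtw(same) < 1e-9))
})

test_that("the vectorized equal-length fast path agrees with per-pair DTW", {
  pop <- make_loop_population(c(u = 12, v = 12), c(u = -5), seed = 206,
                              baseline_target = 1.2)
  D_fast <- pop$matrix
  # force the generic route by perturbing one anchor copy trivially
  loops <- pop$loops
  slow <- vapply(2:length(loops), function(j)
    dtw_distance(loops[[1]], loops[[j]])$distance, numeric(1))
  expect_equal(unname(D_fast[1, -1]), slow, tolerance = 1e-9)
})
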