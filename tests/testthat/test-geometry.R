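# Geometric kernels: superposition, RMSD, minimum distances, contacts and
# radial distribution functions.

test_that("kabsch recovers exact rigid motions and beats random search", {
  set.seed(101)
  cloud <- matrix(rnorm(30, sd = 4), 10)
  tf0 <- kabsch(cloud, cloud)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-10)
  expect_lt(tf0$rmsd, 1e-12)

  R0 <- rand_rotation()
  moved <- sweep(cloud %*% R0, 2, c(3, -2, 7), "+")
  tf <- kabsch(moved, cloud)
  expect_equal(tf$rotation, t(R0), tolerance = 1e-8)
  expect_lt(tf$rmsd, 1e-8)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(tf$rotation), diag(3), tolerance = 1e-9)

  # optimality against a random-search oracle on 100 random instances
  for (k in 1:100) {
    a <- matrix(rnorm(24), 8); b <- matrix(rnorm(24), 8)
    best <- kabsch(a, b)$rmsd
    rand_best <- min(vapply(1:200, function(i)
      rmsd_coords(rand_rigid(a), b), numeric(1)))
    expect_lte(best, rand_best + 1e-9)
  }

  expect_error(kabsch(matrix(rnorm(6), 2), matrix(rnorm(6), 2)), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "degenerate")
})

test_that("rmsd matches its formula and performs no superposition", {
  set.seed(102)
  a <- matrix(rnorm(60), 20)
  expect_equal(rmsd_coords(a, a), 0)
  expect_equal(rmsd_coords(a, sweep(a, 2, c(1, 0, 0), "+")), 1.0)
  for (k in 1:20) {
    b <- matrix(rnorm(60), 20)
    expect_equal(rmsd_coords(a, b), sqrt(mean(rowSums((a - b)^2))),
                 tolerance = 1e-12)
  }
  # a pure rotation changes rmsd (no implicit fitting)
  rot <- a %*% rand_rotation()
  expect_gt(rmsd_coords(a, rot), 0.1)
  expect_error(rmsd_coords(a, matrix(rnorm(30), 10)), "differ")
})

test_that("minimum heavy-atom distance matches brute force and is symmetric", {
  expect_equal(min_heavy_distance(matrix(c(0, 0, 0), 1),
                                  matrix(c(3, 0, 0), 1)), 3.0)
  set.seed(103)
  a <- matrix(rnorm(150, sd = 4), 50)
  b <- matrix(rnorm(150, sd = 4), 50) + 5
  expect_equal(min_heavy_distance(a, b), oracle_min_distance(a, b),
               tolerance = 1e-12)
  expect_equal(min_heavy_distance(a, b), min_heavy_distance(b, a))
  expect_equal(min_heavy_distance(a, rbind(b, a[7, , drop = FALSE])), 0,
               tolerance = 1e-6)   # cancellation noise in the cross term
})

test_that("the contact criterion is a closed bound at 4.5 angstrom", {
  expect_true(in_contact(4.4))
  expect_true(in_contact(4.5))
  expect_false(in_contact(4.6))
  expect_true(in_contact(0))
  expect_error(in_contact(-0.1), "non-negative")
})

test_that("rdf normalization matches the closed form and brute-force counts", {
  # one atom per loop at 5.05 A: only bin [5.0, 5.1) is hit
  items <- list(list(a = matrix(c(0, 0, 0), 1),
                     b = matrix(c(5.05, 0, 0), 1)))
  prof <- rdf_profile(items)
  hit <- which(prof$mean_density > 0)
  expect_equal(prof$bin_edges[hit], 5.0)
  expect_equal(prof$mean_density[hit],
               1 / ((4 / 3) * pi * (5.1^3 - 5.0^3)), tolerance = 1e-12)
  # everything beyond 10 A gives an all-zero profile
  far <- list(list(a = matrix(c(0, 0, 0), 1), b = matrix(c(30, 0, 0), 1)))
  expect_true(all(rdf_profile(far)$mean_density == 0))
  # raw bin counts equal the brute-force histogram
  set.seed(104)
  for (k in 1:5) {
    a <- matrix(rnorm(36, sd = 3), 12); b <- matrix(rnorm(30, sd = 3), 10)
    prof <- rdf_profile(list(list(a = a, b = b)))
    expect_equal(as.vector(prof$counts),
                 oracle_rdf_counts(a, b, prof$bin_edges))
  }
})

test_that("rdf is invariant to rigid motion and to atom duplication", {
  fv <- make_fv(fv_spec(seed = 105))$structure
  p1 <- rdf_profile(list(fv), c("CDR-H3", "CDR-L3"))
  moved <- fv
  xyz <- as.matrix(moved$atoms[, c("x", "y", "z")])
  moved$atoms[, c("x", "y", "z")] <- rand_rigid(xyz)
  p2 <- rdf_profile(list(moved), c("CDR-H3", "CDR-L3"))
  expect_equal(p1$mean_density, p2$mean_density, tolerance = 1e-9)
  # duplicating every atom multiplies counts and possible pairs alike
  a <- select_loop(fv, "CDR-H3", "heavy")$coords
  b <- select_loop(fv, "CDR-L3", "heavy")$coords
  d1 <- rdf_profile(list(list(a = a, b = b)))$mean_density
  d2 <- rdf_profile(list(list(a = rbind(a, a), b = rbind(b, b))))$mean_density
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("per-bin rdf comparison flags planted shifts and nothing else", {
  set.seed(106)
  nb <- 100
  base <- matrix(rnorm(30 * nb, mean = 10, sd = 1), 30)
  a <- structure(list(bin_edges = seq(0, 10, 0.1), density = base,
                      n_items = 30), class = "rdf_profile")
  same <- structure(list(bin_edges = seq(0, 10, 0.1), density = base,
                         n_items = 30), class = "rdf_profile")
  cmp <- rdf_compare(a, same)
  expect_true(all(cmp$p == 1))
  shifted <- base
  shifted[, 42] <- shifted[, 42] * 1.5    # +50% at sigma/mu = 0.1
  b <- structure(list(bin_edges = seq(0, 10, 0.1), density = shifted,
                      n_items = 30), class = "rdf_profile")
  cmp <- rdf_compare(a, b)
  expect_lt(cmp$p[42], 0.01)
  expect_gt(min(cmp$p[-42]), 1e-6)        # no spurious certainty elsewhere
  single <- structure(list(bin_edges = seq(0, 10, 0.1),
                           density = base[1, , drop = FALSE], n_items = 1),
                      class = "rdf_profile")
  expect_error(rdf_compare(a, single), "2 items")
})
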