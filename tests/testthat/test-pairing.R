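# Identical-VH / divergent-VL pairing: alignment identity, greedy
# clustering, pair extraction, region RMSDs and the statistics.

test_that("global identity handles the basic identity arithmetic", {
  expect_equal(global_identity("ACDEFGHIKL", "ACDEFGHIKL"), 100)
  expect_equal(global_identity("AAAA", "AAAT"), 75)
  expect_error(global_identity("", "AAA"), "non-empty")
  expect_error(global_identity("AA1A", "AAA"), "alphabet")
})

test_that("alignment scoring matches an independent Gotoh reimplementation", {
  set.seed(501)
  aln_score <- function(a, b) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = cdrcage:::.aa_submat, gapOpening = 10,
      gapExtension = 1, scoreOnly = TRUE)
  }
  for (k in 1:25) {
    a <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      sample(8:16, 1), replace = TRUE), collapse = "")
    b <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      sample(8:16, 1), replace = TRUE), collapse = "")
    expect_equal(aln_score(a, b), oracle_nw_score(a, b), tolerance = 1e-9)
  }
  # substitution-only pairs: identity is the exact match fraction
  for (k in 1:10) {
    n <- 60
    av <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE)
    bv <- av
    mut <- sample(n, 7)
    for (p in mut) bv[p] <- sample(setdiff(LETTERS[1:20], bv[p]), 1)
    expect_equal(global_identity(paste(av, collapse = ""),
                                 paste(bv, collapse = "")),
                 100 * mean(av == bv), tolerance = 1e-9)
  }
})

test_that("greedy clustering groups planted families deterministically", {
  set.seed(502)
  fam <- paste(sample(LETTERS[1:20], 50, replace = TRUE), collapse = "")
  unrelated <- vapply(1:5, function(i)
    paste(sample(LETTERS[1:20], 50, replace = TRUE), collapse = ""),
    character(1))
  seqs <- c(setNames(rep(fam, 5), paste0("f", 1:5)),
            setNames(unrelated, paste0("u", 1:5)))
  cl <- greedy_cluster(seqs, threshold = 1.0)
  sizes <- sort(vapply(cl, function(x) length(x$members), integer(1)),
                decreasing = TRUE)
  expect_equal(sizes, c(5L, 1L, 1L, 1L, 1L, 1L))
  # all-distinct sequences at threshold 1 stay singletons
  cl2 <- greedy_cluster(setNames(unrelated, paste0("u", 1:5)), 1.0)
  expect_length(cl2, 5L)
  # input order does not change the grouping
  cl3 <- greedy_cluster(rev(seqs), threshold = 1.0)
  mem3 <- sort(vapply(cl3, function(x)
    paste(sort(x$members), collapse = ","), character(1)))
  mem1 <- sort(vapply(cl, function(x)
    paste(sort(x$members), collapse = ","), character(1)))
  expect_equal(mem3, mem1)
})

test_that("pair extraction applies both thresholds and the identity bound", {
  vh <- paste(rep("A", 100), collapse = "")
  vl_base <- paste(sample(LETTERS[1:20], 100, replace = TRUE), collapse = "")
  mutate_at <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (p in seq_len(k)) v[p] <- setdiff(LETTERS[1:20], v[p])[1]
    paste(v, collapse = "")
  }
  rec <- function(id, vh_, vl_) sequence_record(id, vh_, vl_)
  # 95% VL identity with identical VH -> one pair
  r1 <- list(rec("a", vh, vl_base), rec("b", vh, mutate_at(vl_base, 5)))
  p1 <- extract_pairs(r1)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$vl_identity, 95)
  # identical VL -> excluded by the 99% bound
  r2 <- list(rec("a", vh, vl_base), rec("b", vh, vl_base))
  expect_equal(nrow(extract_pairs(r2)), 0L)
  # different VH -> no family, no pair
  vh2 <- paste(rep("C", 100), collapse = "")
  r3 <- list(rec("a", vh, vl_base), rec("b", vh2, mutate_at(vl_base, 5)))
  expect_equal(nrow(extract_pairs(r3)), 0L)
})

test_that("region RMSDs read a planted displacement at fixed framework", {
  base <- make_fv(fv_spec(seed = 503))$structure
  expect_equal(unname(pair_region_rmsd(base, base)), rep(0, 4),
               tolerance = 1e-12)
  # CDR-H3 displaced by 2 A: H3 reads 2, the rest 0
  b <- base
  h3 <- which(b$atoms$chain == "H" &
                assign_region(b$atoms$imgt_number, "H") == "CDR-H3")
  b$atoms[h3, "x"] <- b$atoms[h3, "x"] + 2
  rms <- pair_region_rmsd(base, b)
  expect_equal(unname(rms["CDR-H3"]), 2, tolerance = 1e-6)
  expect_lt(max(rms[c("CDR-H1", "CDR-H2", "FW-H")]), 1e-6)
  # whole-structure rigid motion is removed by the framework alignment
  mv <- base
  mv$atoms[, c("x", "y", "z")] <-
    rand_rigid(as.matrix(mv$atoms[, c("x", "y", "z")]))
  expect_lt(max(pair_region_rmsd(base, mv)), 1e-7)
})

test_that("pearson matches the closed form and behaves under the null", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1.0, tolerance = 1e-12)
  set.seed(504)
  for (k in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    pc <- pearson_cor(a, b)
    expect_equal(pc$r, oracle_pearson(a, b), tolerance = 1e-12)
    ct <- cor.test(a, b)
    expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
  }
  nulls <- vapply(1:50, function(s) {
    set.seed(6000 + s)
    abs(pearson_cor(rnorm(1000), rnorm(1000))$r)
  }, numeric(1))
  expect_gte(mean(nulls < 0.1), 0.99)
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "3 observations")
})

test_that("the canonical-form split test matches exact rank enumeration", {
  pairs <- data.frame(rmsd_h3 = c(1, 2, 3, 4),
                      forms_equal = c(TRUE, TRUE, FALSE, FALSE))
  st <- forms_split_test(pairs, "CDR-H3")
  expect_equal(st$p, 1 / 3, tolerance = 1e-12)
  expect_equal(st$mean_diff, 2)
  expect_true(st$U %in% c(0, 4))
  set.seed(505)
  for (k in 1:15) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    st <- forms_split_test(data.frame(
      rmsd_h3 = c(x, y), forms_equal = rep(c(FALSE, TRUE), c(n1, n2))),
      "CDR-H3")
    expect_equal(st$p, oracle_mw_exact_p(x, y), tolerance = 1e-12)
  }
  # a planted location shift at realistic group sizes is detected
  hits <- 0L
  for (s in 1:20) {
    set.seed(7000 + s)
    eq <- abs(rnorm(58, 1.5, 1)); df <- abs(rnorm(28, 1.5, 1)) + 1.17
    st <- forms_split_test(data.frame(
      rmsd_h3 = c(eq, df), forms_equal = rep(c(TRUE, FALSE), c(58, 28))),
      "CDR-H3")
    if (st$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 16L)   # >= 80% of seeds
})
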