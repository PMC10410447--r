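# The IMGT domain model: region assignment, loop selection and the crystal
# data-set filtering rules.

test_that("region assignment follows the IMGT CDR limits", {
  expect_equal(assign_region(30, "H"), "CDR-H1")
  expect_equal(assign_region(60, "L"), "CDR-L2")
  expect_equal(assign_region(110, "H"), "CDR-H3")
  expect_equal(assign_region(1, "H"), "FW-H")
  expect_error(assign_region(129, "H"), "out of range")
  expect_error(assign_region(0, "L"), "out of range")
})

test_that("every position 1-128 gets exactly one region, with the expected sizes", {
  for (ch in c("H", "L")) {
    regions <- assign_region(1:128, ch)
    expect_length(regions, 128)
    counts <- table(sub("-[HL]", "", sub("CDR-[HL]", "CDR", regions)))
    expect_equal(unname(counts[paste0("CDR", 1:3)]), c(12L, 10L, 13L),
                 ignore_attr = TRUE)
    expect_equal(sum(regions == paste0("FW-", ch)), 93L)
  }
})

test_that("IMGT ordering applies the CDR3 insertion convention", {
  # 111 < 111.1 < 111.2 < 112.2 < 112.1 < 112, elsewhere ascending
  nums <- c(111, 111, 111, 112, 112, 112, 113)
  ins <- c(0, 1, 2, 2, 1, 0, 0)
  keys <- imgt_order_key(nums, ins)
  expect_true(all(diff(keys) > 0))
  expect_true(imgt_order_key(40, 1) > imgt_order_key(40, 0))
  expect_true(imgt_order_key(40, 1) < imgt_order_key(41, 0))
})

test_that("loop selection counts atoms and tolerates missing residues", {
  fv <- make_fv(fv_spec(seed = 21))$structure
  sel <- select_loop(fv, "CDR-H1", "heavy")
  a <- fv$atoms[fv$atoms$chain == "H", ]
  in_h1 <- assign_region(a$imgt_number, "H") == "CDR-H1"
  expect_equal(nrow(sel$coords), sum(in_h1))   # generator atoms are all heavy
  bb <- select_loop(fv, "CDR-L2", "backbone")
  n_res <- length(unique(paste(bb$atoms$imgt_number, bb$atoms$imgt_insertion)))
  expect_equal(nrow(bb$coords), 4 * n_res)
  # removing residue 107 simply shrinks the selection
  fv2 <- fv
  fv2$atoms <- fv2$atoms[!(fv2$atoms$chain == "H" &
                             fv2$atoms$imgt_number == 107), ]
  sel2 <- select_loop(fv2, "CDR-H3", "heavy")
  expect_lt(nrow(sel2$coords), nrow(select_loop(fv, "CDR-H3", "heavy")$coords))
  expect_error(select_loop(fv, "CDR-X9"), "unknown region label")
})

test_that("crystal-set filtering applies each rule and logs rejections", {
  mk <- function(seed, md = list()) {
    make_fv(fv_spec(seed = seed, metadata = md),
            id = paste0("s", seed))$structure
  }
  good <- mk(31)
  nmr <- mk(32, list(method = "SOLUTION NMR"))
  lowres <- mk(33, list(resolution = 3.2))
  nores <- mk(34, list(resolution = NA))
  scfv <- mk(35, list(scfv = TRUE))
  unresolved <- mk(36)
  drop <- which(unresolved$atoms$chain == "L" & unresolved$atoms$atom == "CA" &
                  assign_region(unresolved$atoms$imgt_number, "L") == "CDR-L3")[1]
  unresolved$atoms <- unresolved$atoms[-drop, ]
  single <- mk(37)
  single$atoms <- single$atoms[single$atoms$chain == "H", ]
  dup <- mk(31); dup$id <- "s31_copy"     # identical sequence to `good`

  res <- filter_crystal_set(list(good, nmr, lowres, nores, scfv, unresolved,
                                 single, dup))
  expect_equal(length(res$kept) + nrow(res$log), res$n_input)
  rules <- setNames(res$log$rule, res$log$id)
  expect_equal(unname(rules["s32"]), "method")
  expect_equal(unname(rules["s33"]), "resolution")
  expect_equal(unname(rules["s34"]), "resolution")
  expect_equal(unname(rules["s35"]), "scfv")
  expect_equal(unname(rules["s36"]), "unresolved_loop")
  expect_equal(unname(rules["s37"]), "paired_chains")
  expect_true(any(res$log$rule == "redundancy"))
  expect_length(res$kept, 1L)
})

test_that("filtering is idempotent", {
  structures <- lapply(41:46, function(s)
    make_fv(fv_spec(seed = s), id = paste0("q", s))$structure)
  once <- filter_crystal_set(structures)
  twice <- filter_crystal_set(once$kept)
  expect_equal(length(twice$kept), length(once$kept))
  expect_equal(nrow(twice$log), 0L)
})
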