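test_that("chopping strings parse to ordered, validated annotations", {
  ann <- parse_chopping("1-100/101-200", 200)
  expect_equal(n_domains(ann), 2L)
  expect_equal(format_chopping(ann), "1-100/101-200")

  disc <- parse_chopping("51-150/1-50,151-200", 200)
  # domain starting at residue 1 is labeled first despite input order
  expect_equal(format_chopping(disc), "1-50,151-200/51-150")
  lab <- label_residues(disc)
  expect_equal(lab[1], 1L)
  expect_equal(lab[100], 2L)
  expect_equal(lab[180], 1L)

  expect_error(parse_chopping("1-100/90-200", 200), "overlap")
  expect_error(parse_chopping("100-1", 200), "reversed")
  expect_error(parse_chopping("1-300", 200), "outside")
  expect_error(parse_chopping("1to100", 200), "malformed")
})

test_that("residue labeling marks linkers as NA and shares labels across segments", {
  ann <- parse_chopping("1-100", 100)
  expect_equal(label_residues(ann), rep(1L, 100))

  with_linker <- domain_annotation(list(cbind(1, 100), cbind(111, 200)), 200)
  lab <- label_residues(with_linker)
  expect_true(all(is.na(lab[101:110])))
  expect_equal(lab[150], 2L)
})

test_that("overlap matrix counts jointly labeled residues only", {
  a <- parse_chopping("1-50/51-100", 100)
  m <- overlap_matrix(label_residues(a), label_residues(a))
  expect_equal(unname(m), matrix(c(50L, 0L, 0L, 50L), 2, 2))

  whole <- parse_chopping("1-100", 100)
  m2 <- overlap_matrix(label_residues(a), label_residues(whole))
  expect_equal(unname(m2), matrix(c(50L, 50L), 2, 1))

  none <- rep(NA_integer_, 100)
  expect_equal(dim(overlap_matrix(label_residues(a), none)), c(0L, 0L))
  expect_error(overlap_matrix(1:5, 1:6), "length")
})

test_that("stable marriage: identity on diagonal dominance, swap on anti-diagonal", {
  m <- matrix(c(50, 0, 0, 50), 2, 2)
  expect_equal(stable_marriage_match(m), c(`1` = 1L, `2` = 2L))
  m2 <- matrix(c(0, 70, 60, 0), 2, 2) # ref1 overlaps pred2, ref2 overlaps pred1
  expect_equal(stable_marriage_match(m2), c(`1` = 2L, `2` = 1L))
})

test_that("stable marriage never leaves a blocking pair (enumeration + samples)", {
  # exhaustive 2x2 over entries 0..5
  grid <- expand.grid(a = 0:5, b = 0:5, c = 0:5, d = 0:5)
  for (k in seq_len(nrow(grid))) {
    m <- matrix(as.numeric(grid[k, ]), 2, 2)
    expect_true(is_stable_matching(m, stable_marriage_match(m)))
  }
  # sampled rectangular and larger square matrices, entries 0..5
  set.seed(99)
  for (k in 1:300) {
    nr <- sample(1:4, 1); nc <- sample(1:4, 1)
    m <- matrix(sample(0:5, nr * nc, replace = TRUE), nr, nc)
    expect_true(is_stable_matching(m, stable_marriage_match(m)))
  }
})

test_that("worked NDO case: two 50-residue domains vs one 100-residue domain", {
  ref <- parse_chopping("1-50/51-100", 100)
  pred <- parse_chopping("1-100", 100)
  bal <- ndo_score(ref, pred, "balanced")
  expect_equal(bal$M, 50L)
  expect_equal(bal$l, 100L)
  expect_equal(bal$score, 0)
  frac <- ndo_score(ref, pred, "fraction")
  expect_equal(frac$score, 50)
})

test_that("identical annotations score 100 under both variants", {
  for (chop in c("1-100", "1-50/51-100", "1-30,71-100/31-70")) {
    ann <- parse_chopping(chop, 100)
    expect_equal(ndo_score(ann, ann, "balanced")$score, 100)
    expect_equal(ndo_score(ann, ann, "fraction")$score, 100)
  }
})

test_that("label matching repairs arbitrary label order (swapped-label prediction)", {
  ref <- parse_chopping("1-100/101-200", 200)
  # same partition, but an early discontinuous sliver shifts every label
  pred <- parse_chopping("1-100/101-200", 200)
  pred$domains <- rev(pred$domains) # storage order is irrelevant post-ordering
  expect_equal(ndo_score(ref, pred)$score, 100)
  # a genuinely relabeled prediction: domain 1 discontinuous at 1-5 + 101-200
  pred2 <- parse_chopping("1-5,101-200/6-100", 200)
  res <- ndo_score(ref, pred2)
  # matching must pair ref domain 2 with the discontinuous predicted domain 1
  expect_equal(unname(res$matching[["2"]]), 1L)
  expect_gte(res$score, 90) # only the 5-residue sliver mismatches
})

test_that("scores stay in [0, 100], invariant to predicted label permutation", {
  set.seed(77)
  for (k in 1:50) {
    L <- sample(60:150, 1)
    ref <- random_partition(L)
    pred <- random_partition(L)
    r1 <- ndo_score(ref, pred)
    expect_gte(r1$score, 0)
    expect_lte(r1$score, 100)
    expect_lte(r1$raw, 100)
    # permute predicted domain labels by shuffling storage order
    pred2 <- pred
    pred2$domains <- sample(pred2$domains)
    expect_equal(ndo_score(ref, pred2)$score, r1$score)
  }
})

test_that("relabeling one mismatched residue to its matched label never lowers the score", {
  set.seed(31)
  for (k in 1:30) {
    L <- sample(60:120, 1)
    ref <- random_partition(L)
    pred <- random_partition(L)
    res <- ndo_score(ref, pred)
    if (length(res$matching) == 0) next
    rl <- label_residues(ref); pl <- label_residues(pred)
    match_map <- stats::setNames(as.integer(res$matching),
                                 names(res$matching))
    mismatch <- which(!is.na(rl) & !is.na(pl) &
                        !is.na(match_map[as.character(rl)]) &
                        match_map[as.character(rl)] != pl)
    if (length(mismatch) == 0) next
    p <- sample(mismatch, 1)
    pl2 <- pl
    pl2[p] <- match_map[[as.character(rl[p])]]
    res2 <- ndo_score(ref, labels_to_annotation(pl2))
    expect_gte(res2$score + 1e-9, res$score)
  }
})

test_that("no jointly labeled residue gives score 0 with a warning", {
  ref <- domain_annotation(list(cbind(1, 50)), 100)
  pred <- domain_annotation(list(cbind(51, 100)), 100)
  expect_warning(res <- ndo_score(ref, pred), "no residue")
  expect_equal(res$score, 0)
  expect_error(ndo_score(ref, parse_chopping("1-50", 50)), "lengths differ")
})
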