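test_that("amino-acid composition is a frequency vector", {
  v <- computeAAC("AAAA")
  expect_equal(unname(v["AAC.A"]), 1)
  expect_equal(sum(v), 1)
  expect_true(all(v[names(v) != "AAC.A"] == 0))

  v2 <- computeAAC("ACDE")
  expect_equal(unname(v2[c("AAC.A", "AAC.C", "AAC.D", "AAC.E")]),
               rep(0.25, 4))

  set.seed(1)
  v3 <- computeAAC(randomSeq(1000))
  expect_equal(sum(v3), 1, tolerance = 1e-12)
  expect_error(computeAAC(""), "non-empty")
})

test_that("pseudo amino-acid composition follows the defining formula", {
  set.seed(2)
  s <- randomSeq(40)
  expect_equal(unname(computePAAC(s, lambda = 0)),
               unname(computeAAC(s)))
  # constant sequence: zero property deviations, so the vector is the AAC
  const <- paste(rep("A", 50), collapse = "")
  expect_equal(unname(computePAAC(const, lambda = 5)),
               c(unname(computeAAC(const)), rep(0, 5)))
  for (i in 1:5) {
    s <- randomSeq(100)
    expect_equal(unname(computePAAC(s, lambda = 30, w = 0.05)),
                 oraclePAAC(s, 30, 0.05), tolerance = 1e-9)
  }
  expect_error(computePAAC(randomSeq(20), lambda = 30), "exceed lambda")
})

test_that("amphiphilic PAAC matches its literal implementation", {
  set.seed(3)
  s <- randomSeq(40)
  expect_equal(unname(computeAPAAC(s, lambda = 0)),
               unname(computeAAC(s)))
  expect_length(computeAPAAC(s, lambda = 7), 20 + 14)
  for (i in 1:5) {
    s <- randomSeq(100)
    expect_equal(unname(computeAPAAC(s, lambda = 30, w = 0.05)),
                 oracleAPAAC(s, 30, 0.05), tolerance = 1e-9)
  }
})

test_that("autocorrelation descriptors match direct summation", {
  const <- paste(rep("A", 40), collapse = "")
  v <- computeAutocorrelation(const, maxLag = 4)
  expect_true(all(v[grep("^Moran", names(v))] == 0))
  expect_true(all(v[grep("^Geary", names(v))] == 0))

  set.seed(4)
  expect_length(computeAutocorrelation(randomSeq(60)), 3 * 8 * 30)

  scales <- pf(".autocorrScales")()
  oneProp <- scales[1, , drop = FALSE]
  s <- randomSeq(60)
  v <- computeAutocorrelation(s, properties = oneProp, maxLag = 2)
  for (d in 1:2) {
    o <- oracleAutocorr(s, scales[1, ], d)
    expect_equal(unname(v[sprintf("MB.%s.lag%d",
                                  rownames(scales)[1], d)]),
                 unname(o["mb"]), tolerance = 1e-12)
    expect_equal(unname(v[sprintf("Moran.%s.lag%d",
                                  rownames(scales)[1], d)]),
                 unname(o["moran"]), tolerance = 1e-12)
    expect_equal(unname(v[sprintf("Geary.%s.lag%d",
                                  rownames(scales)[1], d)]),
                 unname(o["geary"]), tolerance = 1e-12)
  }
  expect_error(computeAutocorrelation(randomSeq(10), maxLag = 30),
               "exceed maxLag")
})

test_that("composition/transition/distribution has the documented layout", {
  # lysine is in class 1 of the hydrophobicity grouping (polar)
  v <- computeCTD(paste(rep("K", 10), collapse = ""))
  expect_equal(unname(v[c("CTD.hydrophobicity.comp1",
                          "CTD.hydrophobicity.comp2",
                          "CTD.hydrophobicity.comp3")]), c(1, 0, 0))
  expect_true(all(v[grep("hydrophobicity.trans", names(v))] == 0))
  expect_length(v, 147)

  # A (neutral) and C (hydrophobic) alternate: all 5 adjacent pairs are
  # class-2/class-3 transitions of the hydrophobicity grouping
  v2 <- computeCTD("ACACAC")
  expect_equal(unname(v2["CTD.hydrophobicity.trans3"]), 1)
  expect_error(computeCTD("A"), "length >= 2")
})

test_that("conjoint triad counts cluster triples", {
  v <- computeConjointTriad("ACD")
  expect_length(v, 343)
  expect_equal(sum(v != 0), 1)
  expect_equal(sum(v), 1)
  v2 <- computeConjointTriad("AAAAA")
  expect_equal(unname(v2["CT.1.1.1"]), 1)
  expect_error(computeConjointTriad("AC"), "length >= 3")
})

test_that("quasi-sequence-order matches its literal implementation", {
  # constant sequence: all residue self-distances are zero
  const <- paste(rep("G", 22), collapse = "")
  v <- computeQSO(const, maxLag = 21)
  expect_true(all(v[grep("tau", names(v))] == 0))
  expect_length(v, 124)
  set.seed(5)
  for (i in 1:5) {
    s <- randomSeq(100)
    expect_equal(unname(computeQSO(s, maxLag = 21, w = 0.1)),
                 unname(oracleQSO(s, 21, 0.1)), tolerance = 1e-9)
  }
  expect_error(computeQSO(randomSeq(15), maxLag = 21), "exceed maxLag")
})

test_that("assembled descriptor vector has the seven-class layout", {
  set.seed(6)
  s <- randomSeq(80)
  v <- assembleDescriptorVector(s)
  expect_length(v, 1484)
  spec <- defaultDescriptorSpec()
  expect_equal(spec$total, 1484L)
  expect_equal(vapply(spec$classes, `[[`, 0L, "length"),
               c(20L, 50L, 80L, 720L, 124L, 147L, 343L))
  expect_length(assembleDescriptorVector(
    s, defaultDescriptorSpec(classes = "aac")), 20)
  expect_identical(v, assembleDescriptorVector(s))
  expect_error(assembleDescriptorVector(randomSeq(10)),
               "below the spec minimum")
})

test_that("descriptor classes respond to sequence order as expected", {
  set.seed(7)
  for (i in 1:5) {
    s <- randomSeq(90)
    shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(computeAAC(shuffled), computeAAC(s))
    expect_false(isTRUE(all.equal(
      computeAutocorrelation(shuffled, maxLag = 10),
      computeAutocorrelation(s, maxLag = 10))))
    expect_false(isTRUE(all.equal(computeQSO(shuffled), computeQSO(s))))
    expect_true(all(computeAAC(s) >= 0))
    expect_true(all(computePAAC(s) >= 0))
    expect_true(all(computeConjointTriad(s) >= 0))
  }
})
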