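# shared small fixture: descriptor matrix over an AAC-only spec (fast)
localAacMatrix <- function(n = 8, seed = 10) {
  set.seed(seed)
  computeDescriptorMatrix(randomRecords(n, c(40, 80)),
                          defaultDescriptorSpec(classes = "aac"))
}

test_that("min-max normalization maps features to [0,1] and is frozen", {
  dm <- new("DescriptorMatrix",
            values = cbind(c(2, 4, 6), c(5, 5, 5)),
            proteinIds = c("a", "b", "c"),
            spec = list(classes = list(), total = 2L),
            featMin = numeric(0), featMax = numeric(0),
            normalized = FALSE)
  expect_warning(norm <- normalizeDescriptorMatrix(dm), "constant")
  expect_equal(norm@values[, 1], c(0, 0.5, 1))
  expect_equal(norm@values[, 2], c(0, 0, 0))
  expect_equal(norm@featMin, c(2, 5))
  expect_equal(norm@featMax, c(6, 5))

  dmr <- suppressWarnings(normalizeDescriptorMatrix(localAacMatrix()))
  nonConst <- dmr@featMax > dmr@featMin
  expect_true(all(apply(dmr@values[, nonConst], 2, min) == 0))
  expect_true(all(apply(dmr@values[, nonConst], 2, max) == 1))
})

test_that("cosine distances obey the [0,2] geometry", {
  cosd <- pf(".cosineDistance")
  M <- cbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1), c(-1, -1, 0))
  d <- suppressMessages(cosd(M))
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 1)
  expect_equal(d[1, 4], 2)
  expect_equal(diag(d), rep(0, 4))

  dmr <- suppressWarnings(normalizeDescriptorMatrix(localAacMatrix(10)))
  pdm <- suppressMessages(proteinDistanceMatrix(dmr))
  # loop-wise recomputation oracle
  V <- descriptorValues(dmr)
  for (i in 1:10) for (j in 1:10) {
    expected <- if (i == j) 0 else
      1 - sum(V[i, ] * V[j, ]) / sqrt(sum(V[i, ]^2) * sum(V[j, ]^2))
    expect_equal(pdm[i, j], expected, tolerance = 1e-12)
  }
  expect_lt(max(abs(pdm - t(pdm))), 1e-12)
  fdm <- suppressMessages(featureDistanceMatrix(dmr))
  expect_true(all(fdm >= 0 & fdm <= 2))
  expect_equal(unname(diag(fdm)), rep(0, 20))
})

test_that("2-D reduction is deterministic and preserves collinearity", {
  set.seed(11)
  dmr <- suppressWarnings(normalizeDescriptorMatrix(localAacMatrix(12)))
  fdm <- suppressMessages(featureDistanceMatrix(dmr))
  e1 <- reduceTo2D(fdm, "pca", seed = 3)
  e2 <- reduceTo2D(fdm, "pca", seed = 3)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(20, 2))
  expect_error(reduceTo2D(fdm, "tsne"), "arg")

  # three collinear points stay collinear: verify against a direct
  # eigendecomposition of the centred covariance
  pts <- rbind(c(0, 0, 0), c(1, 2, 3), c(2, 4, 6))
  emb <- reduceTo2D(pts, "pca", seed = 1)
  expect_equal(det(cbind(emb[2, ] - emb[1, ], emb[3, ] - emb[1, ])), 0,
               tolerance = 1e-10)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  proj <- scale(pts, scale = FALSE) %*% ev$vectors[, 1]
  expect_equal(abs(emb[, 1]), abs(as.numeric(proj)), tolerance = 1e-8)
})

test_that("the UMAP reduction runs on a precomputed distance matrix", {
  set.seed(17)
  M <- matrix(runif(900), 30)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  e <- reduceTo2D(M, "umap", seed = 4)
  expect_equal(dim(e), c(30L, 2L))
  expect_true(all(is.finite(e)))
})

test_that("coordinate allocation attains the brute-force optimum", {
  corners <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  map <- allocateCoordinates(corners, gridSide = 2)
  cellOf <- function(r, c, S) (r - 1) * S + c
  expect_setequal(mapAssignment(map), 1:4)
  # each corner point sits in its own quadrant cell
  expect_equal(mapAssignment(map),
               c(cellOf(1, 1, 2), cellOf(1, 2, 2),
                 cellOf(2, 1, 2), cellOf(2, 2, 2)))

  set.seed(12)
  for (rep in 1:6) {
    n <- sample(3:6, 1)
    emb <- matrix(runif(2 * n), ncol = 2)
    S <- 3L
    map <- allocateCoordinates(emb, gridSide = S)
    centers <- cbind(rep((1:S - 0.5) / S, each = S),
                     rep((1:S - 0.5) / S, times = S))
    emb01 <- apply(emb, 2, function(v) (v - min(v)) / (max(v) - min(v)))
    cost <- outer(emb01[, 1], centers[, 1], "-")^2 +
      outer(emb01[, 2], centers[, 2], "-")^2
    achieved <- sum(cost[cbind(seq_len(n), mapAssignment(map))])
    expect_equal(achieved, bruteForceAssignment(cost), tolerance = 1e-12)
  }

  # never worse than 1,000 random injective assignments
  set.seed(13)
  emb <- matrix(runif(100), ncol = 2)
  S <- 8L
  map <- allocateCoordinates(emb, gridSide = S)
  centers <- cbind(rep((1:S - 0.5) / S, each = S),
                   rep((1:S - 0.5) / S, times = S))
  emb01 <- apply(emb, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  cost <- outer(emb01[, 1], centers[, 1], "-")^2 +
    outer(emb01[, 2], centers[, 2], "-")^2
  achieved <- sum(cost[cbind(1:50, mapAssignment(map))])
  randomCosts <- replicate(1000, {
    perm <- sample(S^2, 50)
    sum(cost[cbind(1:50, perm)])
  })
  expect_true(all(achieved <= randomCosts + 1e-12))

  expect_error(allocateCoordinates(matrix(runif(20), ncol = 2),
                                   gridSide = 3), "gridSide >= 4")
})

test_that("template map building is reproducible and serializable", {
  set.seed(14)
  recs <- randomRecords(6, c(40, 60))
  spec <- defaultDescriptorSpec(classes = "aac")
  m1 <- suppressWarnings(suppressMessages(
    buildTemplateMap(recs, spec, seed = 4)))
  m2 <- suppressWarnings(suppressMessages(
    buildTemplateMap(recs, spec, seed = 4)))
  expect_equal(gridSide(m1), 5L) # ceiling(sqrt(20))
  expect_identical(mapAssignment(m1), mapAssignment(m2))

  f <- withr::local_tempfile(fileext = ".json")
  writeTemplateMap(m1, f)
  m3 <- readTemplateMap(f)
  expect_identical(mapAssignment(m1), mapAssignment(m3))
  expect_identical(m1@embedding, m3@embedding)
  expect_identical(m1@featMin, m3@featMin)
  expect_identical(m1@featMax, m3@featMax)
  expect_identical(m1@spec, m3@spec)
  expect_error(buildTemplateMap(recs[1], spec), "cohort")
})

test_that("feature-map images place class intensities at assigned cells", {
  set.seed(15)
  recs <- randomRecords(6, c(40, 60))
  spec <- defaultDescriptorSpec(classes = c("aac", "physicochemical_ctd"))
  map <- suppressWarnings(suppressMessages(
    buildTemplateMap(recs, spec, seed = 5)))
  d <- assembleDescriptorVector(randomSeq(50), spec)
  img <- makeProMap(d, map)
  S <- gridSide(map)
  expect_equal(dim(img), c(2, S, S))
  # all-zero input gives an all-zero tensor
  expect_true(all(makeProMap(rep(0, spec$total), map,
                             normalized = TRUE) == 0))
  # per-channel nonzero support sits inside the class's assigned cells
  cells <- mapAssignment(map)
  for (k in 1:2) {
    cl <- map@spec$classes[[k]]
    classCells <- cells[cl$from:cl$to]
    chan <- img[k, , ]
    nz <- which(t(chan) != 0) # row-major cell index
    expect_true(all(nz %in% classCells))
  }
  # channel partition: nonzero cells = features with nonzero intensity
  v <- pf(".normalizeWith")(matrix(d, 1), map@featMin, map@featMax)
  expect_equal(sum(img != 0), sum(v != 0))
  expect_error(makeProMap(rep(0, 7), map), "does not match")
})

test_that("similarity vectors equal distance-matrix columns and a loop oracle", {
  set.seed(16)
  recs <- randomRecords(10, c(40, 60))
  spec <- defaultDescriptorSpec(classes = c("aac", "qso"))
  dm <- suppressWarnings(normalizeDescriptorMatrix(
    computeDescriptorMatrix(recs, spec)))
  pdm <- suppressMessages(proteinDistanceMatrix(dm))
  v <- makeProSim("p003", dm, pdm)
  expect_equal(unname(v), unname(pdm[, "p003"]))
  expect_equal(unname(v["p003"]), 0)

  # query identical in sequence to a reference protein
  q <- list(id = "q", sequence = recs[[4]]$sequence)
  vq <- makeProSim(q, dm)
  expect_equal(unname(vq["p004"]), 0)

  # random query against the reference matches loop-wise recomputation
  qd <- assembleDescriptorVector(randomSeq(55), spec)
  vr <- makeProSim(qd, dm)
  qn <- pf(".normalizeWith")(matrix(qd, 1), dm@featMin, dm@featMax)
  V <- descriptorValues(dm)
  for (i in 1:10) {
    expected <- 1 - sum(qn * V[i, ]) /
      sqrt(sum(qn^2) * sum(V[i, ]^2))
    expect_equal(unname(vr[i]), expected, tolerance = 1e-12)
  }
  expect_true(all(vr >= 0 & vr <= 2))
})
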