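test_that("similarity transfer weights neighbours by similarity", {
  # 5 reference proteins, 3 labels
  refLabels <- rbind(c(1, 1, 0, 0, 0),
                     c(0, 1, 1, 0, 0),
                     c(0, 0, 0, 1, 1))
  # query identical to reference 2 (distance 0), k = 1
  d <- c(0.8, 0, 0.5, 0.9, 0.7)
  s1 <- similarityTransfer(d, refLabels, k = 1)
  expect_equal(as.numeric(s1), c(1, 1, 0))

  # k = cohort size with equal similarities: per-label frequency
  dEq <- rep(0.5, 5)
  sAll <- similarityTransfer(dEq, refLabels, k = 5)
  expect_equal(as.numeric(sAll), rowMeans(refLabels))

  # k = 2: hand-computed weighted scores; neighbours are refs 2 and 3
  # with sims 1.0 and 0.5
  s2 <- similarityTransfer(d, refLabels, k = 2)
  expect_equal(as.numeric(s2),
               c((1 * 1 + 0.5 * 0) / 1.5,
                 (1 * 1 + 0.5 * 1) / 1.5,
                 0))
  expect_error(similarityTransfer(d, refLabels, k = 6), "exceeds")
})

test_that("ensemble blending is a convex combination", {
  a <- matrix(runif(6), 2)
  b <- matrix(runif(6), 2)
  expect_equal(ensembleCombine(a, b, 1), a)
  expect_equal(ensembleCombine(a, b, 0), b)
  expect_equal(ensembleCombine(a, b, 0.5), (a + b) / 2)
  expect_error(ensembleCombine(a, matrix(0, 3, 2), 0.5), "shape")
  expect_error(ensembleCombine(a, b, 1.2), "alpha")
})

test_that("the ensemble weight maximizes validation Fmax", {
  set.seed(23)
  truth <- list(1:2, 2:3, 1L)
  Y <- matrix(0, 3, 4)
  for (i in 1:3) Y[i, truth[[i]]] <- 1
  dl <- t(Y) * 0.9 + 0.05 # near-perfect deep-learning scores
  sim <- matrix(runif(12), 4, 3) # noise
  sel <- selectEnsembleAlpha(dl, sim, truth)
  expect_gte(sel$alpha, 0.8)
  expect_equal(sel$fmax, 1)
})

test_that("encoder construction matches the documented geometry", {
  mc <- modelConfig(convFilters = c(4L, 6L), embedDim = 16L, seed = 7L)
  enc <- buildEncoder(mc, nLabels = 9L, nChannels = 3L, gridSideLen = 11L,
                      nRef = 20L)
  expect_length(enc$params$fc, 5) # five fully-connected layers
  expect_equal(enc$geom$fcSizes[5], 16L)
  expect_equal(dim(enc$params$refine$W), c(9L, 32L))
  # forward pass shape smoke on a batch of 2
  fwd <- pf(".encoderForward")
  out <- fwd(enc, matrix(runif(3 * 121 * 2), ncol = 2),
             matrix(runif(40), ncol = 2), needCache = FALSE)
  expect_equal(dim(out$logits), c(9L, 2L))
  expect_equal(dim(out$embedding), c(32L, 2L))
  # same seed, same initial parameters
  enc2 <- buildEncoder(mc, 9L, 3L, 11L, 20L)
  expect_identical(enc$params, enc2$params)
  expect_error(buildEncoder(mc, 9L, 3L, 5L, 20L), "too small")
})

test_that("training reduces the loss and is seed-reproducible", {
  set.seed(24)
  mc <- modelConfig(convFilters = c(2L, 3L), embedDim = 8L,
                    maxEpochs = 5L, batchSize = 8L,
                    learningRate = 2e-3, seed = 5L)
  N <- 24
  nLab <- 4L
  enc <- buildEncoder(mc, nLab, nChannels = 1L, gridSideLen = 9L,
                      nRef = 10L)
  cls <- sample(nLab, N, replace = TRUE)
  Ximg <- matrix(0, 81, N)
  for (i in seq_len(N)) # class-specific block pattern plus noise
    Ximg[(cls[i] - 1) * 20 + 1:20, i] <- 1
  Ximg <- Ximg + matrix(runif(81 * N, 0, 0.1), 81, N)
  Xsim <- matrix(runif(10 * N), ncol = N)
  Y <- matrix(0, nLab, N)
  Y[cbind(cls, seq_len(N))] <- 1
  fit <- pretrainEncoder(enc, Ximg, Xsim, Y, mc)
  expect_lt(tail(fit$history$train, 1), fit$history$train[1])
  expect_equal(dim(fit$embeddings), c(16L, N))

  fit2 <- pretrainEncoder(enc, Ximg, Xsim, Y, mc)
  expect_identical(fit$embeddings, fit2$embeddings)
  mcB <- modelConfig(convFilters = c(2L, 3L), embedDim = 8L,
                     maxEpochs = 5L, batchSize = 8L,
                     learningRate = 2e-3, seed = 6L)
  encB <- buildEncoder(mcB, nLab, 1L, 9L, 10L)
  fitB <- pretrainEncoder(encB, Ximg, Xsim, Y, mcB)
  expect_false(identical(fit$embeddings, fitB$embeddings))

  # decoder: training beats the untrained decoder on the same data
  tb <- data.frame(term = paste0("t", 1:4),
                   namespace = "biological_process",
                   level = c(2L, 2L, 3L, 3L), count = 5L, head = FALSE)
  ls <- new("LabelSpace", table = tb, minCount = 1L, anpCutoff = 2000)
  ch <- chunkLabelsByLevel(ls, T = 3L)
  mcD <- modelConfig(lstmUnits = 16L, maxEpochs = 10L, batchSize = 8L,
                     learningRate = 5e-3, seed = 5L)
  dec0 <- list(geom = list(inputDim = 16L, H = 16L, L = 3L, T = 3L,
                           chunkSizes = ch$chunkSizes,
                           chunkIdx = ch$chunkIdx),
               params = pf(".decoderInit")(
                 list(inputDim = 16L, H = 16L, L = 3L, T = 3L,
                      chunkSizes = ch$chunkSizes), 5L))
  truth <- apply(Y > 0, 2, which, simplify = FALSE)
  fm0 <- computeFmax(t(decoderScores(dec0, fit$embeddings)), truth)
  fitD <- trainDecoder(fit$embeddings, Y, ch, mcD)
  expect_equal(fitD$decoder$geom$L, 3L)
  fm1 <- computeFmax(t(decoderScores(fitD$decoder, fit$embeddings)),
                     truth)
  expect_gt(fm1$fmax, fm0$fmax)
})

test_that("hierarchical consistency raises ancestors to descendant scores", {
  g <- assignLevels(toyGraphFixture())
  tb <- data.frame(term = c("a", "b", "c", "d"),
                   namespace = "biological_process",
                   level = c(2L, 2L, 3L, 4L), count = 5L, head = FALSE)
  ls <- new("LabelSpace", table = tb, minCount = 1L, anpCutoff = 2000)
  s <- matrix(c(0.1, 0.0, 0.2, 0.9), 4, 1)
  out <- pf(".hierarchicalMax")(s, ls, g)
  # d = 0.9 propagates through c to both diamond parents a and b
  expect_equal(as.numeric(out), c(0.9, 0.9, 0.9, 0.9))
  s2 <- matrix(c(0.5, 0.4, 0.3, 0.2), 4, 1)
  expect_equal(as.numeric(pf(".hierarchicalMax")(s2, ls, g)),
               c(0.5, 0.4, 0.3, 0.2))
})

test_that("label-frequency prior repeats training frequencies", {
  Y <- cbind(c(1, 0, 1), c(1, 1, 0))
  out <- labelFrequencyBaseline(Y, 4)
  expect_equal(dim(out), c(3L, 4L))
  expect_equal(out[, 3], c(1, 0.5, 0.5))
})
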