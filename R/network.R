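#' Model hyperparameter configuration
#'
#' Returns the model configuration with documented defaults. Convolution
#' kernel 3x3 with stride 1, two convolution and two max-pooling layers
#' (pool length 2, stride 1, i.e. overlapping pooling), ReLU activations;
#' five fully-connected layers on the similarity-vector path; a three-layer
#' LSTM with 256 units per layer and Tanh activations unrolled over 11 time
#' steps; mini-batch size 32 and learning rate 0.0002 (Adam) for both
#' training stages; focal loss with gamma 2 and alpha 0.25; early stopping
#' on the validation loss with patience 10. Convolution filter counts
#' (32, 64) and the 512-wide per-path embedding are free defaults.
#'
#' @param ... overrides for any field.
#' @return named list of hyperparameters.
#' @export
modelConfig <- function(...) {
  cfg <- list(
    convKernel = 3L, convStride = 1L, convFilters = c(32L, 64L),
    poolSize = 2L, poolStride = 1L,
    fcLayers = 5L, embedDim = 512L,
    lstmLayers = 3L, lstmUnits = 256L, timeSteps = 11L,
    batchSize = 32L, learningRate = 2e-4,
    focalGamma = 2, focalAlpha = 0.25,
    patience = 10L, maxEpochs = 60L,
    hierConsistency = TRUE, ensembleK = 30L,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(all(vapply(cfg[c("convKernel", "poolSize", "fcLayers",
                             "lstmLayers", "lstmUnits", "timeSteps",
                             "batchSize", "learningRate")],
                       function(v) all(v > 0), TRUE)))
  if (cfg$convStride != 1L || cfg$poolStride != 1L)
    stop("only stride 1 is implemented for convolution and pooling")
  cfg
}

#' Build the dual-path encoder
#'
#' Constructs the untrained encoder: a multi-channel CNN over feature-map
#' images (conv 3x3/s1, maxpool 2/s1, conv, maxpool, flatten, dense; ReLU
#' throughout), a five-layer fully-connected path over protein-similarity
#' vectors (widths tapering geometrically from the input to the embedding
#' width), concatenation of the two path embeddings, and a fully-connected
#' refinement head onto the label space used for pre-training.
#'
#' @param config a [modelConfig()].
#' @param nLabels number of label-space terms (or a [LabelSpace-class]).
#' @param nChannels,gridSideLen image geometry (channels x side x side).
#' @param nRef length of the protein-similarity vector.
#' @return encoder as `list(geom, params)`; parameters are initialized
#'   reproducibly from `config$seed`.
#' @export
buildEncoder <- function(config, nLabels, nChannels, gridSideLen, nRef) {
  if (is(nLabels, "LabelSpace")) nLabels <- nrow(nLabels@table)
  k <- config$convKernel
  pool <- config$poolSize
  OH1 <- gridSideLen - k + 1
  PH1 <- OH1 - pool + 1
  OH2 <- PH1 - k + 1
  PH2 <- OH2 - pool + 1
  if (PH2 < 1)
    stop("grid side ", gridSideLen, " too small for two conv/pool stages")
  E <- config$embedDim
  nFc <- config$fcLayers
  fcSizes <- round(nRef * (E / nRef)^(seq_len(nFc) / nFc))
  fcSizes[nFc] <- E
  fcSizes <- pmax(fcSizes, 2L)
  geom <- list(C = nChannels, S = gridSideLen,
               F1 = config$convFilters[1], F2 = config$convFilters[2],
               convKernel = k, poolSize = pool,
               OH1 = OH1, PH1 = PH1, OH2 = OH2, PH2 = PH2,
               flatDim = config$convFilters[2] * PH2^2,
               nFc = nFc, fcSizes = fcSizes, E = E,
               nRef = nRef, nLabels = nLabels)
  list(geom = geom, params = .encoderInit(geom, config$seed))
}

.minibatches <- function(idx, batchSize) {
  split(idx, ceiling(seq_along(idx) / batchSize))
}

.encoderLossOver <- function(enc, Ximg, Xsim, Y, idx, config) {
  tot <- 0
  for (b in .minibatches(idx, 256L)) {
    fw <- .encoderForward(enc, Ximg[, b, drop = FALSE],
                          Xsim[, b, drop = FALSE], needCache = FALSE)
    fb <- .focalForwardBackward(fw$logits, Y[, b, drop = FALSE],
                                config$focalGamma, config$focalAlpha)
    tot <- tot + fb$loss * length(b)
  }
  tot / length(idx)
}

#' Pre-train the dual-path encoder against GO labels
#'
#' Multi-label training with the focal loss, Adam (mini-batch 32, learning
#' rate 0.0002 by default) and early stopping on the validation loss.
#' Returns the trained encoder and the frozen concatenated embeddings of
#' every protein.
#'
#' @param encoder from [buildEncoder()].
#' @param promaps numeric matrix, flattened feature-map images
#'   (channels*side*side) x proteins.
#' @param prosims numeric matrix, similarity vectors (nRef x proteins).
#' @param labels binary matrix, labels x proteins.
#' @param config a [modelConfig()].
#' @param trainIdx,valIdx column indices of the training/validation split;
#'   with `valIdx = NULL` no early stopping is applied (overfit mode).
#' @param verbose print per-epoch losses.
#' @return `list(encoder, embeddings, history)`.
#' @export
pretrainEncoder <- function(encoder, promaps, prosims, labels, config,
                            trainIdx = NULL, valIdx = NULL,
                            verbose = FALSE) {
  N <- ncol(promaps)
  if (is.null(trainIdx)) trainIdx <- seq_len(N)
  state <- .adamInit(encoder$params)
  best <- encoder$params
  bestVal <- Inf
  wait <- 0L
  hist <- list()
  set.seed(config$seed)
  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample(trainIdx)
    epochLoss <- 0
    for (b in .minibatches(ord, config$batchSize)) {
      fw <- .encoderForward(encoder, promaps[, b, drop = FALSE],
                            prosims[, b, drop = FALSE])
      fb <- .focalForwardBackward(fw$logits, labels[, b, drop = FALSE],
                                  config$focalGamma, config$focalAlpha)
      if (!is.finite(fb$loss))
        stop("encoder training diverged at epoch ", epoch,
             " (non-finite loss)")
      grads <- .encoderBackward(encoder, fb$dlogits, fw$cache)
      upd <- .adamStep(encoder$params, grads, state, config$learningRate)
      encoder$params <- upd$params
      state <- upd$state
      epochLoss <- epochLoss + fb$loss * length(b)
    }
    epochLoss <- epochLoss / length(trainIdx)
    valLoss <- if (length(valIdx))
      .encoderLossOver(encoder, promaps, prosims, labels, valIdx, config)
    else NA_real_
    hist[[epoch]] <- c(epoch = epoch, train = epochLoss, val = valLoss)
    if (verbose)
      message(sprintf("encoder epoch %d: train %.5f val %.5f", epoch,
                      epochLoss, valLoss))
    if (length(valIdx)) {
      if (valLoss < bestVal - 1e-7) {
        bestVal <- valLoss
        best <- encoder$params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }
  if (length(valIdx)) encoder$params <- best
  emb <- matrix(0, 2 * encoder$geom$E, N)
  for (b in .minibatches(seq_len(N), 256L))
    emb[, b] <- .encoderForward(encoder, promaps[, b, drop = FALSE],
                                prosims[, b, drop = FALSE],
                                needCache = FALSE)$embedding
  list(encoder = encoder, embeddings = emb,
       history = as.data.frame(do.call(rbind, hist)))
}

#' Partition the label space into ordered level chunks
#'
#' Buckets the (level-ordered) label space into `T` chunks for the LSTM
#' decoder: chunk t holds the terms of the t-th shallowest level present;
#' levels beyond the T-th are merged into the last chunk. Chunks are
#' disjoint, their union is the whole label space, and the order runs
#' shallow to deep.
#'
#' @param labelSpace a [LabelSpace-class].
#' @param T number of time steps (default 11).
#' @return `list(chunkIdx, chunkSizes, chunkLevels)`; `chunkIdx[[t]]` are
#'   row indices into the label table.
#' @export
chunkLabelsByLevel <- function(labelSpace, T = 11L) {
  stopifnot(T >= 1)
  lv <- labelSpace@table$level
  uniq <- sort(unique(lv))
  chunkIdx <- rep(list(integer(0)), T)
  for (k in seq_along(uniq)) {
    t <- min(k, T)
    chunkIdx[[t]] <- c(chunkIdx[[t]], which(lv == uniq[k]))
  }
  list(chunkIdx = chunkIdx,
       chunkSizes = lengths(chunkIdx),
       chunkLevels = lapply(seq_len(T), function(t)
         sort(unique(lv[chunkIdx[[t]]]))))
}

#' Train the level-wise LSTM decoder
#'
#' A three-layer LSTM (256 units per layer, Tanh activations) consumes the
#' frozen encoder embedding at step 1 (zero input afterwards, state-carried
#' decoding) and at step t emits sigmoid scores for the t-th level chunk of
#' the label space. The focal loss is summed over steps; Adam, mini-batch
#' 32, learning rate 0.0002, early stopping on validation loss.
#'
#' @param embeddings numeric matrix (embedding dim x proteins), frozen.
#' @param labels binary matrix, labels x proteins.
#' @param chunks from [chunkLabelsByLevel()].
#' @param config a [modelConfig()].
#' @param trainIdx,valIdx split column indices (see [pretrainEncoder()]).
#' @param verbose print per-epoch losses.
#' @return `list(decoder, history)`.
#' @export
trainDecoder <- function(embeddings, labels, chunks, config,
                         trainIdx = NULL, valIdx = NULL, verbose = FALSE) {
  N <- ncol(embeddings)
  if (is.null(trainIdx)) trainIdx <- seq_len(N)
  geom <- list(inputDim = nrow(embeddings), H = config$lstmUnits,
               L = config$lstmLayers, T = length(chunks$chunkIdx),
               chunkSizes = chunks$chunkSizes, chunkIdx = chunks$chunkIdx)
  dec <- list(geom = geom, params = .decoderInit(geom, config$seed))
  state <- .adamInit(dec$params)
  best <- dec$params
  bestVal <- Inf
  wait <- 0L
  hist <- list()
  lossOver <- function(idx) {
    tot <- 0
    for (b in .minibatches(idx, 256L)) {
      fw <- .decoderForward(dec, embeddings[, b, drop = FALSE],
                            needCache = FALSE)
      l <- 0
      for (t in seq_len(geom$T)) {
        if (!geom$chunkSizes[t]) next
        Yt <- labels[geom$chunkIdx[[t]], b, drop = FALSE]
        l <- l + .focalForwardBackward(fw$logits[[t]], Yt,
                                       config$focalGamma,
                                       config$focalAlpha)$loss
      }
      tot <- tot + l * length(b)
    }
    tot / length(idx)
  }
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample(trainIdx)
    epochLoss <- 0
    for (b in .minibatches(ord, config$batchSize)) {
      fw <- .decoderForward(dec, embeddings[, b, drop = FALSE])
      loss <- 0
      dlogits <- vector("list", geom$T)
      for (t in seq_len(geom$T)) {
        if (!geom$chunkSizes[t]) next
        Yt <- labels[geom$chunkIdx[[t]], b, drop = FALSE]
        fb <- .focalForwardBackward(fw$logits[[t]], Yt,
                                    config$focalGamma, config$focalAlpha)
        loss <- loss + fb$loss
        dlogits[[t]] <- fb$dlogits
      }
      if (!is.finite(loss))
        stop("decoder training diverged at epoch ", epoch,
             " (non-finite loss)")
      grads <- .decoderBackward(dec, dlogits, fw$cache)
      upd <- .adamStep(dec$params, grads, state, config$learningRate)
      dec$params <- upd$params
      state <- upd$state
      epochLoss <- epochLoss + loss * length(b)
    }
    epochLoss <- epochLoss / length(trainIdx)
    valLoss <- if (length(valIdx)) lossOver(valIdx) else NA_real_
    hist[[epoch]] <- c(epoch = epoch, train = epochLoss, val = valLoss)
    if (verbose)
      message(sprintf("decoder epoch %d: train %.5f val %.5f", epoch,
                      epochLoss, valLoss))
    if (length(valIdx)) {
      if (valLoss < bestVal - 1e-7) {
        bestVal <- valLoss
        best <- dec$params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }
  if (length(valIdx)) dec$params <- best
  list(decoder = dec, history = as.data.frame(do.call(rbind, hist)))
}

#' Score proteins with a trained decoder
#'
#' @param decoder from [trainDecoder()].
#' @param embeddings embedding matrix (dim x proteins).
#' @return score matrix, labels x proteins, in [0,1].
#' @export
decoderScores <- function(decoder, embeddings) {
  g <- decoder$geom
  N <- ncol(embeddings)
  out <- matrix(0, sum(g$chunkSizes), N)
  for (b in .minibatches(seq_len(N), 256L)) {
    fw <- .decoderForward(decoder, embeddings[, b, drop = FALSE],
                          needCache = FALSE)
    for (t in seq_len(g$T)) {
      if (!g$chunkSizes[t]) next
      out[g$chunkIdx[[t]], b] <- .sigmoid(fw$logits[[t]])
    }
  }
  out
}

#' Sequence-similarity annotation transfer
#'
#' Scores a query against the label space from its k most similar reference
#' proteins: `score(q, t) = sum_k sim * 1[t annotated] / sum_k sim` with
#' `sim = 1 - cosine distance`, clipped to [0,1].
#'
#' @param prosim numeric matrix of cosine distances, nRef x nQueries (a
#'   single vector is accepted).
#' @param refLabels binary matrix, labels x nRef.
#' @param k number of neighbours (default 30; must not exceed nRef).
#' @return score matrix, labels x nQueries.
#' @export
similarityTransfer <- function(prosim, refLabels, k = 30L) {
  if (is.null(dim(prosim))) prosim <- matrix(prosim, ncol = 1)
  nRef <- nrow(prosim)
  if (k > nRef)
    stop("k (", k, ") exceeds the reference cohort size (", nRef, ")")
  sims <- pmin(pmax(1 - prosim, 0), 1)
  out <- matrix(0, nrow(refLabels), ncol(prosim))
  for (j in seq_len(ncol(prosim))) {
    s <- sims[, j]
    nn <- order(s, decreasing = TRUE)[seq_len(k)]
    w <- s[nn]
    if (sum(w) > 0)
      out[, j] <- as.numeric(refLabels[, nn, drop = FALSE] %*% w) / sum(w)
  }
  out
}

#' Blend deep-learning and similarity scores
#'
#' `alpha * dl + (1 - alpha) * sim`, elementwise on matching matrices.
#'
#' @param dlScores,simScores score matrices of identical shape.
#' @param alpha mixing weight in [0,1].
#' @return blended score matrix.
#' @export
ensembleCombine <- function(dlScores, simScores, alpha) {
  if (!identical(dim(dlScores), dim(simScores)))
    stop("score matrices must have identical shape")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  alpha * dlScores + (1 - alpha) * simScores
}

#' Choose the ensemble weight on validation Fmax
#'
#' Scans `alphaGrid` and returns the weight maximizing the protein-centric
#' Fmax of the blended scores on the validation set (ties resolved towards
#' larger alpha).
#'
#' @param dlScores,simScores labels x proteins validation score matrices.
#' @param truth list of per-protein true term-index sets (see
#'   [computeFmax()]) or a binary matrix.
#' @param alphaGrid candidate weights.
#' @return `list(alpha, fmax)`.
#' @export
selectEnsembleAlpha <- function(dlScores, simScores, truth,
                                alphaGrid = seq(0, 1, by = 0.1)) {
  fm <- vapply(alphaGrid, function(a) {
    computeFmax(t(ensembleCombine(dlScores, simScores, a)), truth)$fmax
  }, 0)
  best <- max(which(fm == max(fm)))
  list(alpha = alphaGrid[best], fmax = fm[best])
}

# enforce the true-path rule on scores: each term's score becomes the max
# over itself and its descendants inside the label space (deep to shallow)
.hierarchicalMax <- function(scores, labelSpace, graph) {
  terms <- labelSpace@table$term
  inSpace <- stats::setNames(seq_along(terms), terms)
  ord <- order(labelSpace@table$level, decreasing = TRUE)
  for (i in ord) {
    ps <- intersect(graph@parents[[terms[i]]], terms)
    for (p in ps) {
      j <- inSpace[[p]]
      scores[j, ] <- pmax(scores[j, ], scores[i, ])
    }
  }
  scores
}

#' Label-frequency prior baseline
#'
#' Assigns every protein the training-set frequency of each label -- the
#' naive predictor that a long-tail-aware model must beat.
#'
#' @param refLabels binary matrix, labels x reference proteins.
#' @param n number of query proteins.
#' @return score matrix, labels x n.
#' @export
labelFrequencyBaseline <- function(refLabels, n) {
  matrix(rep(rowMeans(refLabels), n), ncol = n)
}
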