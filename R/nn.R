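# Minimal neural-network engine used by the encoder/decoder. Activations
# are stored one sample per column (D x N matrices). All gradients are
# hand-derived and checked against numerical differentiation in the tests.

.relu <- function(x) x * (x > 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(nOut, nIn) {
  lim <- sqrt(6 / (nIn + nOut))
  matrix(stats::runif(nOut * nIn, -lim, lim), nOut, nIn)
}

#' Focal loss for multi-label classification
#'
#' Element-wise focal loss
#' `-alpha * y * (1-p)^gamma * log(p) - (1-alpha) * (1-y) * p^gamma * log(1-p)`.
#' At `gamma = 0`, `alpha = 0.5` this is half the binary cross-entropy. The
#' down-weighting of well-classified examples is what makes the loss usable
#' on long-tailed label distributions dominated by easy negatives.
#'
#' @param p predicted probabilities in (0,1).
#' @param y binary targets (same shape).
#' @param gamma focusing exponent (default 2).
#' @param alpha positive-class weight (default 0.25).
#' @return numeric of the same shape as `p`.
#' @export
focalLoss <- function(p, y, gamma = 2, alpha = 0.25) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -alpha * y * (1 - p)^gamma * log(p) -
    (1 - alpha) * (1 - y) * p^gamma * log(1 - p)
}

# loss (mean over columns of the per-sample label sum) and gradient with
# respect to the logits
.focalForwardBackward <- function(logits, Y, gamma, alpha) {
  N <- ncol(logits)
  p <- .sigmoid(logits)
  loss <- sum(focalLoss(p, Y, gamma, alpha)) / N
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  gPos <- alpha * (gamma * pc * (1 - pc)^gamma * log(pc) -
                     (1 - pc)^(gamma + 1))
  gNeg <- (1 - alpha) * (pc^(gamma + 1) -
                           gamma * (1 - pc) * pc^gamma * log(1 - pc))
  dlogits <- (Y * gPos + (1 - Y) * gNeg) / N
  list(loss = loss, dlogits = dlogits, p = p)
}

# ---- parameter-tree utilities (nested lists of numeric arrays) ----------

.treeMap <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1))
    return(stats::setNames(
      lapply(seq_along(t1), function(k)
        do.call(.treeMap, c(list(f), lapply(trees, `[[`, k)))),
      names(t1)))
  do.call(f, trees)
}

.treeZero <- function(params) .treeMap(function(x) x * 0, params)

.adamInit <- function(params)
  list(m = .treeZero(params), v = .treeZero(params), t = 0L)

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .treeMap(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- .treeMap(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- .treeMap(function(p, m, v)
    p - lr * (m / c1) / (sqrt(v / c2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

# ---- dual-path encoder ---------------------------------------------------

# reshape conv output (F x N*OH*OW) to pooling layout (F*OH*OW x N)
.convReshape <- function(Z, Fn, OH, OW, N) {
  arr <- array(Z, dim = c(Fn, OW, OH, N))
  arr <- aperm(arr, c(2, 3, 1, 4))
  dim(arr) <- c(Fn * OH * OW, N)
  arr
}

.convReshapeBwd <- function(dR, Fn, OH, OW, N) {
  arr <- array(dR, dim = c(OW, OH, Fn, N))
  arr <- aperm(arr, c(3, 1, 2, 4))
  dim(arr) <- c(Fn, N * OH * OW)
  arr
}

.encoderInit <- function(geom, seed) {
  set.seed(seed)
  k <- geom$convKernel
  params <- list(
    conv1 = list(W = .glorot(geom$F1, geom$C * k * k),
                 b = numeric(geom$F1)),
    conv2 = list(W = .glorot(geom$F2, geom$F1 * k * k),
                 b = numeric(geom$F2)),
    dense = list(W = .glorot(geom$E, geom$flatDim), b = numeric(geom$E)),
    fc = lapply(seq_len(geom$nFc), function(l) {
      nIn <- if (l == 1) geom$nRef else geom$fcSizes[l - 1]
      list(W = .glorot(geom$fcSizes[l], nIn),
           b = numeric(geom$fcSizes[l]))
    }),
    refine = list(W = .glorot(geom$nLabels, 2 * geom$E),
                  b = numeric(geom$nLabels))
  )
  params
}

.encoderForward <- function(enc, Ximg, Xsim, needCache = TRUE) {
  g <- enc$geom
  p <- enc$params
  N <- ncol(Ximg)
  k <- g$convKernel
  P1 <- im2col_cpp(Ximg, g$C, g$S, g$S, k, k)
  Z1 <- p$conv1$W %*% P1 + p$conv1$b
  R1 <- .convReshape(.relu(Z1), g$F1, g$OH1, g$OH1, N)
  pool1 <- maxpool_cpp(R1, g$F1, g$OH1, g$OH1, g$poolSize)
  P2 <- im2col_cpp(pool1$out, g$F1, g$PH1, g$PH1, k, k)
  Z2 <- p$conv2$W %*% P2 + p$conv2$b
  R2 <- .convReshape(.relu(Z2), g$F2, g$OH2, g$OH2, N)
  pool2 <- maxpool_cpp(R2, g$F2, g$OH2, g$OH2, g$poolSize)
  Zd <- p$dense$W %*% pool2$out + p$dense$b
  Eimg <- .relu(Zd)
  H <- Xsim
  Zf <- hid <- vector("list", g$nFc)
  for (l in seq_len(g$nFc)) {
    hid[[l]] <- H
    Zf[[l]] <- p$fc[[l]]$W %*% H + p$fc[[l]]$b
    H <- .relu(Zf[[l]])
  }
  Z <- rbind(Eimg, H)
  logits <- p$refine$W %*% Z + p$refine$b
  cache <- if (needCache)
    list(P1 = P1, Z1 = Z1, pool1 = pool1, P2 = P2, Z2 = Z2,
         pool2 = pool2, Zd = Zd, Zf = Zf, hid = hid, Z = Z, N = N)
  else NULL
  list(logits = logits, embedding = Z, cache = cache)
}

.encoderBackward <- function(enc, dlogits, cache) {
  g <- enc$geom
  p <- enc$params
  N <- cache$N
  Z <- cache$Z
  grads <- list()
  grads$refine <- list(W = dlogits %*% t(Z), b = rowSums(dlogits))
  dZ <- crossprod(p$refine$W, dlogits)
  dEimg <- dZ[seq_len(g$E), , drop = FALSE]
  dH <- dZ[g$E + seq_len(g$E), , drop = FALSE]
  grads$fc <- vector("list", g$nFc)
  for (l in rev(seq_len(g$nFc))) {
    dZf <- dH * (cache$Zf[[l]] > 0)
    grads$fc[[l]] <- list(W = dZf %*% t(cache$hid[[l]]),
                          b = rowSums(dZf))
    dH <- crossprod(p$fc[[l]]$W, dZf)
  }
  dZd <- dEimg * (cache$Zd > 0)
  grads$dense <- list(W = dZd %*% t(cache$pool2$out), b = rowSums(dZd))
  dO2 <- crossprod(p$dense$W, dZd)
  dR2 <- maxpool_bwd_cpp(dO2, cache$pool2$argmax,
                         g$F2 * g$OH2 * g$OH2)
  dZ2 <- .convReshapeBwd(dR2, g$F2, g$OH2, g$OH2, N) * (cache$Z2 > 0)
  grads$conv2 <- list(W = dZ2 %*% t(cache$P2), b = rowSums(dZ2))
  dP2 <- crossprod(p$conv2$W, dZ2)
  dO1 <- col2im_cpp(dP2, g$F1, g$PH1, g$PH1, g$convKernel, g$convKernel, N)
  dR1 <- maxpool_bwd_cpp(dO1, cache$pool1$argmax,
                         g$F1 * g$OH1 * g$OH1)
  dZ1 <- .convReshapeBwd(dR1, g$F1, g$OH1, g$OH1, N) * (cache$Z1 > 0)
  grads$conv1 <- list(W = dZ1 %*% t(cache$P1), b = rowSums(dZ1))
  grads[c("conv1", "conv2", "dense", "fc", "refine")]
}

# ---- LSTM decoder --------------------------------------------------------

.decoderInit <- function(geom, seed) {
  set.seed(seed)
  H <- geom$H
  lstm <- lapply(seq_len(geom$L), function(l) {
    nIn <- if (l == 1) geom$inputDim else H
    b <- numeric(4 * H)
    b[H + seq_len(H)] <- 1 # forget-gate bias 1
    list(W = .glorot(4 * H, nIn), U = .glorot(4 * H, H), b = b)
  })
  heads <- lapply(geom$chunkSizes, function(m)
    list(W = .glorot(max(m, 1L), H)[seq_len(m), , drop = FALSE],
         b = numeric(m)))
  list(lstm = lstm, heads = heads)
}

.lstmCellForward <- function(lp, inp, hPrev, cPrev, H) {
  gates <- lp$W %*% inp + lp$U %*% hPrev + lp$b
  i <- .sigmoid(gates[seq_len(H), , drop = FALSE])
  f <- .sigmoid(gates[H + seq_len(H), , drop = FALSE])
  g <- tanh(gates[2 * H + seq_len(H), , drop = FALSE])
  o <- .sigmoid(gates[3 * H + seq_len(H), , drop = FALSE])
  c <- f * cPrev + i * g
  tc <- tanh(c)
  h <- o * tc
  list(i = i, f = f, g = g, o = o, c = c, tc = tc, h = h,
       inp = inp, hPrev = hPrev, cPrev = cPrev)
}

.decoderForward <- function(dec, X, needCache = TRUE) {
  g <- dec$geom
  p <- dec$params
  H <- g$H
  N <- ncol(X)
  zero <- matrix(0, H, N)
  zeroIn <- matrix(0, g$inputDim, N)
  h <- c <- rep(list(zero), g$L)
  caches <- vector("list", g$T)
  logits <- vector("list", g$T)
  for (t in seq_len(g$T)) {
    inp <- if (t == 1) X else zeroIn
    stepCache <- vector("list", g$L)
    for (l in seq_len(g$L)) {
      cell <- .lstmCellForward(p$lstm[[l]], inp, h[[l]], c[[l]], H)
      h[[l]] <- cell$h
      c[[l]] <- cell$c
      inp <- cell$h
      stepCache[[l]] <- cell
    }
    logits[[t]] <- if (g$chunkSizes[t] > 0)
      p$heads[[t]]$W %*% h[[g$L]] + p$heads[[t]]$b else
      matrix(0, 0, N)
    if (needCache) caches[[t]] <- stepCache
  }
  list(logits = logits, cache = if (needCache) caches else NULL)
}

.decoderBackward <- function(dec, dlogitsList, cache) {
  g <- dec$geom
  p <- dec$params
  H <- g$H
  N <- ncol(cache[[1]][[1]]$h)
  zero <- matrix(0, H, N)
  dh <- dc <- rep(list(zero), g$L)
  grads <- .treeZero(p)
  for (t in rev(seq_len(g$T))) {
    if (g$chunkSizes[t] > 0) {
      dlg <- dlogitsList[[t]]
      hTop <- cache[[t]][[g$L]]$h
      grads$heads[[t]]$W <- grads$heads[[t]]$W + dlg %*% t(hTop)
      grads$heads[[t]]$b <- grads$heads[[t]]$b + rowSums(dlg)
      dh[[g$L]] <- dh[[g$L]] + crossprod(p$heads[[t]]$W, dlg)
    }
    for (l in rev(seq_len(g$L))) {
      cell <- cache[[t]][[l]]
      dho <- dh[[l]]
      do <- dho * cell$tc
      dcl <- dc[[l]] + dho * cell$o * (1 - cell$tc^2)
      di <- dcl * cell$g
      df <- dcl * cell$cPrev
      dg <- dcl * cell$i
      dgates <- rbind(di * cell$i * (1 - cell$i),
                      df * cell$f * (1 - cell$f),
                      dg * (1 - cell$g^2),
                      do * cell$o * (1 - cell$o))
      grads$lstm[[l]]$W <- grads$lstm[[l]]$W + dgates %*% t(cell$inp)
      grads$lstm[[l]]$U <- grads$lstm[[l]]$U + dgates %*% t(cell$hPrev)
      grads$lstm[[l]]$b <- grads$lstm[[l]]$b + rowSums(dgates)
      dinp <- crossprod(p$lstm[[l]]$W, dgates)
      dh[[l]] <- crossprod(p$lstm[[l]]$U, dgates) # carry to t-1
      dc[[l]] <- dcl * cell$f
      # input of layer l is layer l-1's hidden state at the same step;
      # layer 1's input gradient would flow to the frozen embedding
      if (l > 1) dh[[l - 1]] <- dh[[l - 1]] + dinp
    }
  }
  grads
}
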