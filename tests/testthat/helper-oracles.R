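# Literal-from-formula reference implementations, written independently of
# the package code paths, plus small fixture builders shared across tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomSeq <- function(len) paste(sample(AA20, len, replace = TRUE),
                                 collapse = "")

randomRecords <- function(n, lenRange = c(60, 150)) {
  lapply(seq_len(n), function(i)
    list(id = sprintf("p%03d", i),
         sequence = randomSeq(sample(lenRange[1]:lenRange[2], 1))))
}

# package-internal helpers used by the oracles (property scales only)
pf <- function(name) getFromNamespace(name, "ProFunMap")

# type-I pseudo amino-acid composition, straight from the defining formula
oraclePAAC <- function(sequence, lambda, w) {
  x <- strsplit(sequence, "")[[1]]
  L <- length(x)
  scales <- pf(".paacScales")()
  f <- sapply(AA20, function(a) sum(x == a) / L)
  theta <- numeric(lambda)
  for (k in seq_len(lambda)) {
    s <- 0
    for (i in seq_len(L - k)) {
      s <- s + mean((scales[, x[i]] - scales[, x[i + k]])^2)
    }
    theta[k] <- s / (L - k)
  }
  denom <- sum(f) + w * sum(theta)
  unname(c(f / denom, w * theta / denom))
}

# amphiphilic pseudo amino-acid composition from the defining formula
oracleAPAAC <- function(sequence, lambda, w) {
  x <- strsplit(sequence, "")[[1]]
  L <- length(x)
  scales <- pf(".paacScales")()
  f <- sapply(AA20, function(a) sum(x == a) / L)
  tau <- numeric(2 * lambda)
  for (k in seq_len(lambda)) {
    h1 <- h2 <- 0
    for (i in seq_len(L - k)) {
      h1 <- h1 + scales["hydrophobicity", x[i]] *
        scales["hydrophobicity", x[i + k]]
      h2 <- h2 + scales["hydrophilicity", x[i]] *
        scales["hydrophilicity", x[i + k]]
    }
    tau[2 * k - 1] <- h1 / (L - k)
    tau[2 * k] <- h2 / (L - k)
  }
  denom <- sum(f) + w * sum(tau)
  unname(c(f / denom, w * tau / denom))
}

# Moreau-Broto / Moran / Geary autocorrelation by direct summation
oracleAutocorr <- function(sequence, scale, d) {
  x <- strsplit(sequence, "")[[1]]
  L <- length(x)
  v <- scale[x]
  vbar <- mean(v)
  mb <- sum(sapply(seq_len(L - d), function(i) v[i] * v[i + d])) / (L - d)
  moran <- (sum(sapply(seq_len(L - d), function(i)
    (v[i] - vbar) * (v[i + d] - vbar))) / (L - d)) /
    (sum((v - vbar)^2) / L)
  geary <- (sum(sapply(seq_len(L - d), function(i)
    (v[i] - v[i + d])^2)) / (2 * (L - d))) /
    (sum((v - vbar)^2) / (L - 1))
  c(mb = mb, moran = moran, geary = geary)
}

# quasi-sequence-order from the defining formula, given distance matrices
oracleQSO <- function(sequence, maxLag, w) {
  x <- strsplit(sequence, "")[[1]]
  L <- length(x)
  mats <- list(pf(".granthamDistance")(), pf(".physchemDistance")())
  f <- sapply(AA20, function(a) sum(x == a) / L)
  taus <- lapply(mats, function(D)
    sapply(seq_len(maxLag), function(d)
      sum(sapply(seq_len(L - d), function(i) D[x[i], x[i + d]]^2))))
  qsos <- lapply(taus, function(tau)
    c(f, w * tau) / (sum(f) + w * sum(tau)))
  c(unlist(taus), unlist(qsos))
}

# exhaustive minimum-cost injective assignment (n <= 6 features)
bruteForceAssignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) {
      best <<- acc
      return()
    }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1, used, acc + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1, logical(m), 0)
  best
}

# brute-force protein-centric Fmax by direct looping
bruteForceFmax <- function(pred, truthList, thresholds) {
  keep <- lengths(truthList) > 0
  pred <- pred[keep, , drop = FALSE]
  truthList <- truthList[keep]
  bestF <- 0
  for (th in thresholds) {
    prs <- c()
    rcs <- c()
    for (i in seq_len(nrow(pred))) {
      P <- which(pred[i, ] >= th)
      T <- truthList[[i]]
      if (length(P)) prs <- c(prs, length(intersect(P, T)) / length(P))
      rcs <- c(rcs, length(intersect(P, T)) / length(T))
    }
    pr <- if (length(prs)) mean(prs) else 0
    rc <- mean(rcs)
    f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    bestF <- max(bestF, f)
  }
  bestF
}

# brute-force micro AUPRC: walk the score-sorted pair list, group ties
bruteForceAUPRC <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  scores <- scores[o]
  labels <- labels[o]
  P <- sum(labels)
  area <- 0
  prevRec <- 0
  i <- 1
  tp <- 0
  n <- 0
  while (i <= length(scores)) {
    j <- i
    while (j <= length(scores) && scores[j] == scores[i]) j <- j + 1
    tp <- tp + sum(labels[i:(j - 1)])
    n <- n + (j - i)
    rec <- tp / P
    prec <- tp / n
    area <- area + (rec - prevRec) * prec
    prevRec <- rec
    i <- j
  }
  area
}

# a 12-term, hand-checkable ontology: one BP chain with a diamond and a
# long path (levels known by inspection), one MF pair, one CC pair
toyGraphFixture <- function() {
  terms <- data.frame(
    id = c("R:BP", "a", "b", "c", "d", "e", "f", "g",
           "R:MF", "m1", "R:CC", "c1"),
    name = paste("term", 1:12),
    namespace = c(rep("biological_process", 8), "molecular_function",
                  "molecular_function", "cellular_component",
                  "cellular_component"))
  parents <- list(
    "R:BP" = character(0),
    a = "R:BP",              # level 2
    b = "R:BP",              # level 2
    c = c("a", "b"),         # diamond -> level 3
    d = "c",                 # level 4
    e = "d",                 # level 5
    f = c("a", "e"),         # parents at levels 2 and 5 -> level 3
    g = "f",                 # level 4
    "R:MF" = character(0),
    m1 = "R:MF",             # level 2
    "R:CC" = character(0),
    c1 = "R:CC")             # level 2
  new("GeneOntologyGraph", terms = terms, parents = parents,
      roots = c(biological_process = "R:BP",
                molecular_function = "R:MF",
                cellular_component = "R:CC"),
      level = integer(0))
}

annotationFixture <- function(pairs) {
  new("AnnotationTable",
      pairs = data.frame(protein = pairs[, 1], term = pairs[, 2]),
      propagated = FALSE)
}
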