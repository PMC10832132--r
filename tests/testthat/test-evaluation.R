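test_that("Fmax handles perfect, empty and hand-checked predictors", {
  pred <- rbind(p1 = c(1, 0, 0), p2 = c(1, 1, 0))
  colnames(pred) <- c("g1", "g2", "g3")
  truth <- list(1L, c(1L, 2L))
  expect_equal(computeFmax(pred, truth)$fmax, 1)
  expect_equal(computeFmax(pred * 0, truth)$fmax, 0)

  pred2 <- rbind(p1 = c(0.9, 0.4, 0.1), p2 = c(0.8, 0.7, 0.2))
  fm <- computeFmax(pred2, truth)
  expect_equal(fm$fmax,
               bruteForceFmax(pred2, truth, seq(0.01, 1, by = 0.01)),
               tolerance = 1e-12)
  # proteins with empty truth are excluded with a warning
  expect_warning(fm2 <- computeFmax(pred2, list(1L, integer(0))),
                 "excluded")
  expect_equal(fm2$fmax, computeFmax(pred2[1, , drop = FALSE],
                                     list(1L))$fmax)
})

test_that("AUPRC integrates the tie-grouped precision-recall staircase", {
  pred <- matrix(seq(1, 0.1, length.out = 10), 1)
  truth <- matrix(0, 1, 10)
  truth[1, 1:3] <- 1
  expect_equal(computeAUPRC(pred, truth), 1) # perfect ranking
  truthLast <- matrix(0, 1, 10)
  truthLast[1, 10] <- 1
  expect_equal(computeAUPRC(pred, truthLast), 1 / 10)

  # 6-pair toy, hand-traced staircase
  p6 <- matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), 1)
  y6 <- matrix(c(1, 0, 0, 1, 0, 0), 1)
  # recall steps at 0.5 (prec 1/1) and 1.0 (prec 2/4)
  expect_equal(computeAUPRC(p6, y6), 0.5 * 1 + 0.5 * 0.5)
  expect_error(computeAUPRC(p6, y6 * 0), "no positive")
})

test_that("metrics agree with brute-force references on random instances", {
  set.seed(30)
  for (rep in 1:50) {
    nP <- sample(2:6, 1)
    nT <- sample(3:7, 1)
    pred <- matrix(round(runif(nP * nT), 2), nP, nT)
    truth <- lapply(seq_len(nP), function(i)
      sample(nT, sample(1:nT, 1)))
    fm <- computeFmax(pred, truth)
    expect_equal(fm$fmax,
                 bruteForceFmax(pred, truth, seq(0.01, 1, by = 0.01)),
                 tolerance = 1e-10)
    Y <- matrix(0, nP, nT)
    for (i in seq_len(nP)) Y[i, truth[[i]]] <- 1
    expect_equal(computeAUPRC(pred, Y),
                 bruteForceAUPRC(as.numeric(pred), as.numeric(Y)),
                 tolerance = 1e-10)
    # ROC AUC equals the normalized Mann-Whitney U statistic
    s <- as.numeric(pred)
    y <- as.numeric(Y)
    if (any(y > 0) && any(y == 0)) {
      w <- stats::wilcox.test(s[y > 0], s[y == 0], exact = FALSE)
      expect_equal(pf(".rocAUC")(s, y),
                   unname(w$statistic) / (sum(y > 0) * sum(y == 0)),
                   tolerance = 1e-10)
    }
  }
})

test_that("per-protein recall and precision follow the set definitions", {
  pred <- rbind(p1 = c(1, 1, 0, 0), p2 = c(1, 1, 1, 1))
  colnames(pred) <- paste0("g", 1:4)
  truth <- list(c(1L, 2L), c(1L, 2L))
  rp <- proteinRecallPrecision(pred, truth, threshold = 0.5)
  expect_equal(rp$recall, c(1, 1))
  expect_equal(rp$precision, c(1, 0.5))
  rp0 <- proteinRecallPrecision(pred * 0, truth, threshold = 0.5)
  expect_true(all(is.na(rp0$precision)))
  expect_equal(rp0$recall, c(0, 0))
})

test_that("level-stratified AUC matches rank-sum computation", {
  g <- assignLevels(toyGraphFixture())
  set.seed(31)
  # 8 proteins, one term: AUC by hand via rank sums
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2)
  y <- c(1, 0, 1, 0, 0, 1, 0, 0)
  pred <- matrix(s, 8, 1, dimnames = list(paste0("p", 1:8), "m1"))
  Y <- matrix(y, 8, 1, dimnames = dimnames(pred))
  out <- levelAUC(pred, Y, g)
  r <- rank(s)
  expect_equal(out$auc,
               (sum(r[y == 1]) - 3 * 4 / 2) / (3 * 5), tolerance = 1e-12)
  expect_equal(out$level, 2L)

  # perfectly separating scores
  Yp <- matrix(as.numeric(s > 0.55), 8, 1, dimnames = dimnames(pred))
  expect_equal(levelAUC(pred, Yp, g)$auc, 1)

  # chance level on random balanced scores (2000 proteins)
  predR <- matrix(runif(2000), 2000, 1,
                  dimnames = list(paste0("q", 1:2000), "m1"))
  YR <- matrix(rbinom(2000, 1, 0.5), 2000, 1,
               dimnames = dimnames(predR))
  expect_lt(abs(levelAUC(predR, YR, g)$auc - 0.5), 0.05)

  # independent library cross-check on one random instance
  if (requireNamespace("pROC", quietly = TRUE)) {
    sc <- runif(60)
    lab <- rbinom(60, 1, 0.4)
    expect_equal(pf(".rocAUC")(sc, lab),
                 as.numeric(pROC::auc(pROC::roc(lab, sc,
                                                quiet = TRUE))),
                 tolerance = 1e-10)
  }
})

test_that("Fmax is invariant to monotone transforms on a quantile grid", {
  set.seed(32)
  pred <- matrix(runif(40), 5, 8)
  truth <- lapply(1:5, function(i) sample(8, 3))
  qs <- unique(stats::quantile(pred, seq(0, 1, by = 0.05)))
  f1 <- computeFmax(pred, truth, thresholds = qs)$fmax
  trans <- pred^3 # strictly monotone
  qs2 <- unique(stats::quantile(trans, seq(0, 1, by = 0.05)))
  f2 <- computeFmax(trans, truth, thresholds = qs2)$fmax
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("the evaluation report separates namespaces and head/tail", {
  g <- assignLevels(toyGraphFixture())
  prots <- paste0("p", 1:6)
  terms <- c("a", "c", "m1")
  set.seed(33)
  pairs <- rbind(cbind(prots[1:4], "c"), cbind(prots[3:6], "m1"))
  tab <- propagateAnnotations(annotationFixture(pairs), g)
  pred <- matrix(runif(18), 6, 3, dimnames = list(prots, terms)) * 0.5
  keep <- tab@pairs$term %in% terms
  pred[cbind(match(tab@pairs$protein[keep], prots),
             match(tab@pairs$term[keep], terms))] <- 0.95
  rep <- evaluateReport(pred, tab, g, anpCutoff = 4)
  expect_setequal(names(rep$perNamespace),
                  c("biological_process", "molecular_function"))
  expect_gte(rep$perNamespace$biological_process$fmax, 0.9)
  expect_true(all(rep$levelAUC$auc >= 0 & rep$levelAUC$auc <= 1))
  expect_true(all(rep$levelAUC$group %in% c("head", "tail")))
})
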