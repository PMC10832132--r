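# normalize truth input (binary matrix or per-protein list of column
# indices / term names) to a binary matrix aligned with `predictions`
.truthMatrix <- function(predictions, truth) {
  if (is.matrix(truth)) {
    stopifnot(identical(dim(truth), dim(predictions)))
    return((truth > 0) + 0)
  }
  stopifnot(length(truth) == nrow(predictions))
  Y <- matrix(0, nrow(predictions), ncol(predictions),
              dimnames = dimnames(predictions))
  for (i in seq_along(truth)) {
    tt <- truth[[i]]
    if (is.character(tt)) tt <- match(tt, colnames(predictions))
    tt <- tt[!is.na(tt)]
    Y[i, tt] <- 1
  }
  Y
}

#' Protein-centric maximum F-measure (Fmax)
#'
#' Scans a threshold grid; at threshold t the precision is averaged over
#' proteins with at least one prediction scoring >= t, the recall over all
#' benchmark proteins, and Fmax is the largest harmonic mean of the two.
#' Proteins with an empty truth set are excluded with a warning.
#'
#' @param predictions numeric matrix of scores, proteins x terms.
#' @param truth binary matrix of the same shape, or a per-protein list of
#'   true term indices or names.
#' @param thresholds numeric grid (default 0.01, 0.02, ..., 1.00).
#' @return `list(fmax, threshold, curve)` where `curve` holds precision and
#'   recall per scanned threshold.
#' @export
computeFmax <- function(predictions, truth,
                        thresholds = seq(0.01, 1, by = 0.01)) {
  Y <- .truthMatrix(predictions, truth)
  tSize <- rowSums(Y)
  if (any(tSize == 0)) {
    warning(sum(tSize == 0), " protein(s) with empty truth set excluded")
    keep <- tSize > 0
    predictions <- predictions[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
    tSize <- tSize[keep]
  }
  if (!nrow(predictions))
    return(list(fmax = 0, threshold = NA_real_,
                curve = data.frame(threshold = numeric(0))))
  pr <- rc <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    B <- predictions >= thresholds[k]
    tp <- rowSums(B & (Y > 0))
    pSize <- rowSums(B)
    covered <- pSize > 0
    pr[k] <- if (any(covered)) mean(tp[covered] / pSize[covered]) else 0
    rc[k] <- mean(tp / tSize)
  }
  f <- ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)
  best <- which.max(f)
  list(fmax = f[best],
       threshold = if (f[best] > 0) thresholds[best] else NA_real_,
       curve = data.frame(threshold = thresholds, precision = pr,
                          recall = rc, f = f))
}

#' Micro-averaged area under the precision-recall curve
#'
#' Pools all (protein, term) pairs, ranks them by score, groups ties, and
#' integrates the right-continuous (step-wise) precision-recall staircase.
#'
#' @inheritParams computeFmax
#' @return numeric scalar in [0,1].
#' @export
computeAUPRC <- function(predictions, truth) {
  Y <- .truthMatrix(predictions, truth)
  s <- as.numeric(predictions)
  y <- as.numeric(Y)
  P <- sum(y)
  if (P == 0) stop("AUPRC undefined: no positive (protein, term) pair")
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  y <- y[ord]
  grp <- cumsum(!duplicated(s))
  tpGrp <- tapply(y, grp, sum)
  nGrp <- tapply(y, grp, length)
  cumTP <- cumsum(tpGrp)
  cumN <- cumsum(nGrp)
  prec <- cumTP / cumN
  rec <- cumTP / P
  sum(diff(c(0, rec)) * prec)
}

#' Per-protein recall and precision at a threshold
#'
#' `recall = |P & T| / |T|` and `precision = |P & T| / |P|` per protein,
#' with precision reported as `NA` when the protein has no prediction at
#' the threshold.
#'
#' @inheritParams computeFmax
#' @param threshold score cutoff in (0,1].
#' @return data.frame with columns protein, recall, precision.
#' @export
proteinRecallPrecision <- function(predictions, truth, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  Y <- .truthMatrix(predictions, truth)
  B <- predictions >= threshold
  tp <- rowSums(B & (Y > 0))
  pSize <- rowSums(B)
  tSize <- rowSums(Y)
  data.frame(
    protein = rownames(predictions) %||% as.character(seq_len(nrow(Y))),
    recall = ifelse(tSize > 0, tp / tSize, NA_real_),
    precision = ifelse(pSize > 0, tp / pSize, NA_real_)
  )
}

# rank-based ROC AUC (equals the normalized Mann-Whitney U statistic)
.rocAUC <- function(scores, labels) {
  nPos <- sum(labels > 0)
  nNeg <- sum(labels <= 0)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels > 0]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Level-stratified term-centric ROC AUC
#'
#' For every term at a hierarchy level, computes the ROC AUC of its scores
#' over proteins (positives = annotated, negatives = not), then
#' macro-averages within the level. Terms lacking both classes are skipped
#' and counted; levels without any valid term are omitted.
#'
#' @inheritParams computeFmax
#' @param graph a [GeneOntologyGraph-class] with levels; `predictions` must
#'   have term ids as column names.
#' @return data.frame with columns level, auc, nTerms, nSkipped.
#' @export
levelAUC <- function(predictions, truth, graph) {
  if (is.null(colnames(predictions)))
    stop("predictions need term ids as column names")
  if (!length(graph@level)) stop("assign levels first")
  Y <- .truthMatrix(predictions, truth)
  lv <- graph@level[colnames(predictions)]
  if (anyNA(lv))
    stop("term(s) absent from ontology: ",
         paste(utils::head(colnames(predictions)[is.na(lv)], 3),
               collapse = ", "))
  out <- list()
  for (l in sort(unique(lv))) {
    cols <- which(lv == l)
    aucs <- vapply(cols, function(j) .rocAUC(predictions[, j], Y[, j]), 0)
    valid <- !is.na(aucs)
    if (!any(valid)) next
    out[[length(out) + 1]] <- data.frame(
      level = l, auc = mean(aucs[valid]), nTerms = sum(valid),
      nSkipped = sum(!valid))
  }
  do.call(rbind, out)
}

#' Full evaluation report
#'
#' Per-namespace Fmax (with its optimal threshold) and micro-averaged
#' AUPRC, the level-stratified AUC table, and a head/tail summary that
#' averages the level AUCs within head and tail label levels (head = level
#' average protein count >= `anpCutoff` in the truth annotations).
#'
#' @param predictions score matrix, proteins x terms (term-id colnames).
#' @param tab a propagated [AnnotationTable-class] restricted to the
#'   benchmark proteins.
#' @param graph a [GeneOntologyGraph-class] with levels.
#' @param anpCutoff head/tail boundary (default 2000, inclusive).
#' @return nested list: `perNamespace`, `levelAUC`, `headTail`.
#' @export
evaluateReport <- function(predictions, tab, graph, anpCutoff = 2000) {
  stopifnot(is(tab, "AnnotationTable"), isTRUE(tab@propagated))
  prots <- rownames(predictions)
  terms <- colnames(predictions)
  Y <- matrix(0, length(prots), length(terms),
              dimnames = dimnames(predictions))
  keep <- tab@pairs$protein %in% prots & tab@pairs$term %in% terms
  Y[cbind(tab@pairs$protein[keep], tab@pairs$term[keep])] <- 1
  ns <- stats::setNames(graph@terms$namespace, graph@terms$id)[terms]
  perNs <- lapply(split(seq_along(terms), ns), function(cols) {
    p <- predictions[, cols, drop = FALSE]
    y <- Y[, cols, drop = FALSE]
    nonEmpty <- rowSums(y) > 0
    if (!any(nonEmpty)) return(NULL)
    fm <- suppressWarnings(computeFmax(p, y))
    list(fmax = fm$fmax, threshold = fm$threshold,
         auprc = computeAUPRC(p[nonEmpty, , drop = FALSE],
                              y[nonEmpty, , drop = FALSE]),
         nProteins = sum(nonEmpty))
  })
  lvl <- levelAUC(predictions, Y, graph)
  anp <- anpPerLevel(tab, graph)
  ht <- classifyHeadTail(anp, cutoff = anpCutoff)
  lvl$group <- unname(ht[as.character(lvl$level)])
  headTail <- tapply(lvl$auc, lvl$group, mean)
  list(perNamespace = perNs[!vapply(perNs, is.null, TRUE)],
       levelAUC = lvl, headTail = headTail)
}
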