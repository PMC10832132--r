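#' Generate a toy GO-like ontology
#'
#' Builds a random is_a DAG over up to three namespaces: one root per
#' namespace, each further term attached to a uniformly drawn parent of
#' the same namespace whose level is below `maxDepth`, with an occasional
#' second parent (a multi-parent diamond). Terms only point at
#' earlier-created terms, so the graph is acyclic by construction.
#'
#' @param nTerms total number of terms (>= maxDepth and >= nNamespaces).
#' @param maxDepth deepest allowed level (>= 2).
#' @param seed integer seed.
#' @param nNamespaces 1 to 3 namespaces.
#' @param diamondProb probability of a second parent (default 0.2).
#' @return A [GeneOntologyGraph-class] (levels not yet assigned).
#' @export
generateToyOntology <- function(nTerms = 40, maxDepth = 6, seed = 1L,
                                nNamespaces = 3, diamondProb = 0.2) {
  if (maxDepth < 2 || nTerms < maxDepth || nTerms < nNamespaces)
    stop("need nTerms >= maxDepth >= 2 and nTerms >= nNamespaces")
  set.seed(seed)
  nsNames <- c("biological_process", "molecular_function",
               "cellular_component")[seq_len(nNamespaces)]
  ids <- sprintf("G:%07d", seq_len(nTerms))
  nss <- character(nTerms)
  parents <- stats::setNames(vector("list", nTerms), ids)
  level <- integer(nTerms)
  nss[seq_len(nNamespaces)] <- nsNames
  level[seq_len(nNamespaces)] <- 1L
  for (k in seq_len(nNamespaces)) parents[[k]] <- character(0)
  for (k in seq_len(nTerms)[-seq_len(nNamespaces)]) {
    ns <- nsNames[(k - 1) %% nNamespaces + 1]
    nss[k] <- ns
    eligible <- which(nss[seq_len(k - 1)] == ns &
                        level[seq_len(k - 1)] < maxDepth)
    p1 <- if (length(eligible) == 1) eligible else sample(eligible, 1)
    ps <- ids[p1]
    level[k] <- level[p1] + 1L
    others <- setdiff(which(nss[seq_len(k - 1)] == ns), p1)
    if (length(others) && stats::runif(1) < diamondProb) {
      p2 <- if (length(others) == 1) others else sample(others, 1)
      ps <- c(ps, ids[p2])
      level[k] <- min(level[k], level[p2] + 1L)
    }
    parents[[k]] <- ps
  }
  terms <- data.frame(id = ids, name = paste("toy term", seq_len(nTerms)),
                      namespace = nss)
  roots <- stats::setNames(ids[seq_len(nNamespaces)], nsNames)
  new("GeneOntologyGraph", terms = terms, parents = parents,
      roots = roots, level = integer(0))
}

# leaves of the ontology ordered shallow to deep (then by id): the planted
# family-size ranking follows this order
.ontologyLeaves <- function(graph) {
  withKids <- unique(unlist(graph@parents, use.names = FALSE))
  leaves <- setdiff(graph@terms$id, c(withKids, graph@roots))
  lv <- assignLevels(graph)@level
  leaves[order(lv[leaves], leaves)]
}

#' Generate a protein cohort with planted function signals
#'
#' Each protein carries 1-3 leaf-term labels; leaf prevalence decays as a
#' power law in the leaf's rank (shallow leaves common, deep leaves rare),
#' realizing a long-tailed family-size distribution whose counts are
#' non-increasing in rank by construction. A protein's sequence is drawn
#' from a background residue distribution tilted towards each of its
#' leaves' two bias residues, and each leaf's distinct sequence motif is
#' written into the sequence several times, so the labels are recoverable
#' from sequence composition and short matches.
#'
#' @param n cohort size.
#' @param graph toy ontology from [generateToyOntology()].
#' @param seed integer seed.
#' @param lengthRange sequence length range (default 60-200).
#' @param prevalenceExponent power-law exponent of leaf prevalence
#'   (default 1.5).
#' @param motifLength,motifCopies planted motif geometry (default 6 and 3).
#' @param biasStrength multiplicative tilt of the two bias residues
#'   (default 3).
#' @param meanLabels expected labels per protein (in [1,3], default 1.8).
#' @return `list(records, annotations, motifTable)`; `annotations` is the
#'   direct (unpropagated) truth.
#' @export
generateCohort <- function(n, graph, seed = 1L, lengthRange = c(60, 200),
                           prevalenceExponent = 1.5, motifLength = 6,
                           motifCopies = 3, biasStrength = 3,
                           meanLabels = 1.8) {
  set.seed(seed)
  if (motifLength >= lengthRange[1])
    stop("motif longer than the minimum sequence length")
  leaves <- .ontologyLeaves(graph)
  nl <- length(leaves)
  if (nl < 2) stop("ontology has too few leaves")
  # distinct motif and two bias residues per leaf
  motifs <- character(nl)
  repeat {
    motifs <- vapply(seq_len(nl), function(i)
      paste(sample(.AA, motifLength, replace = TRUE), collapse = ""), "")
    if (!anyDuplicated(motifs)) break
  }
  biasRes <- lapply(seq_len(nl), function(i) sample(.AA, 2))
  # labels per protein: 1..3 with the configured mean (1 + p + p/2)
  p2 <- min(max((meanLabels - 1) / 1.5, 0), 1)
  nLab <- 1L + stats::rbinom(n, 1L, p2) + stats::rbinom(n, 1L, p2 / 2)
  nLab <- pmin(nLab, 3L)
  S <- sum(nLab)
  # largest-remainder apportionment of S slots over power-law weights
  wts <- seq_len(nl)^(-prevalenceExponent)
  quota <- wts / sum(wts) * S
  cnt <- floor(quota)
  rem <- S - sum(cnt)
  if (rem > 0) {
    extra <- order(quota - cnt, seq_len(nl), decreasing = c(TRUE, FALSE),
                   method = "radix")[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  # a family cannot exceed the cohort size; push overflow down the ranks
  # without breaking the non-increasing order
  excess <- sum(pmax(cnt - n, 0))
  cnt <- pmin(cnt, n)
  for (r in seq_len(nl)) {
    room <- (if (r > 1) min(n, cnt[r - 1]) else n) - cnt[r]
    add <- min(room, excess)
    cnt[r] <- cnt[r] + add
    excess <- excess - add
  }
  # deal slots to proteins: always take distinct leaves with the largest
  # remaining counts (ties towards smaller rank) so counts stay monotone
  remCnt <- cnt
  labels <- vector("list", n)
  for (i in sample.int(n)) {
    take <- utils::head(order(-remCnt, seq_len(nl)),
                        min(nLab[i], sum(remCnt > 0)))
    take <- take[remCnt[take] > 0]
    if (!length(take)) take <- 1L
    labels[[i]] <- take
    remCnt[take] <- remCnt[take] - 1L
  }
  # repair any rank inversion the leftover slots may have caused
  actual <- tabulate(unlist(labels), nbins = nl)
  for (r in seq_len(nl - 1)) {
    while (actual[r] < actual[r + 1]) {
      cand <- which(vapply(labels, function(l)
        (r + 1) %in% l && !(r %in% l), TRUE))[1]
      labels[[cand]][labels[[cand]] == r + 1] <- r
      actual[r] <- actual[r] + 1L
      actual[r + 1] <- actual[r + 1] - 1L
    }
  }
  # sequences: tilted background + planted motifs
  baseFreq <- rep(1, 20)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    L <- sample(lengthRange[1]:lengthRange[2], 1)
    w <- baseFreq
    for (r in labels[[i]])
      w[match(biasRes[[r]], .AA)] <- w[match(biasRes[[r]], .AA)] *
        biasStrength
    chars <- sample(.AA, L, replace = TRUE, prob = w / sum(w))
    # plant motifs at mutually non-overlapping positions so no later copy
    # clobbers an earlier leaf's motif; the first copy per leaf is
    # guaranteed, extra copies are best-effort
    occupied <- logical(L)
    plant <- function(r) {
      starts <- which(vapply(seq_len(L - motifLength + 1), function(p)
        !any(occupied[p:(p + motifLength - 1)]), TRUE))
      if (!length(starts)) return(FALSE)
      pos <- if (length(starts) == 1) starts else sample(starts, 1)
      span <- pos:(pos + motifLength - 1)
      chars[span] <<- strsplit(motifs[r], "")[[1]]
      occupied[span] <<- TRUE
      TRUE
    }
    for (r in labels[[i]]) plant(r) # one guaranteed copy per leaf
    for (r in labels[[i]])
      for (cpy in seq_len(motifCopies - 1)) plant(r)
    records[[i]] <- list(id = sprintf("prot%04d", i),
                         sequence = paste(chars, collapse = ""))
  }
  pairs <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(protein = records[[i]]$id, term = leaves[labels[[i]]])))
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  motifTable <- data.frame(term = leaves, motif = motifs,
                           biasResidues = vapply(biasRes, paste, "",
                                                 collapse = ""),
                           plantedCount = actual)
  list(records = records,
       annotations = new("AnnotationTable", pairs = pairs,
                         propagated = FALSE),
       motifTable = motifTable)
}

#' Random, reproducible cohort split
#'
#' Disjoint, exhaustive assignment of proteins to the named fractions
#' (default the 80/20 train/validation split).
#'
#' @param ids protein ids.
#' @param fractions named numeric summing to 1, each in (0,1).
#' @param seed integer seed.
#' @return named character vector, id -> split name.
#' @export
splitCohort <- function(ids, fractions = c(train = 0.8, validation = 0.2),
                        seed = 1L) {
  if (any(fractions <= 0) || any(fractions >= 1))
    stop("every fraction must lie strictly between 0 and 1")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1")
  set.seed(seed)
  n <- length(ids)
  sizes <- floor(fractions * n)
  leftover <- n - sum(sizes)
  if (leftover > 0) {
    top <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(leftover)]
    sizes[top] <- sizes[top] + 1L
  }
  assignment <- rep(names(fractions), sizes)
  stats::setNames(assignment[sample.int(n)], ids)
}

#' Generate the default synthetic benchmark
#'
#' A self-contained desk-scale benchmark: a toy three-namespace ontology,
#' a cohort with planted motif/composition signals (n = 500, sequence
#' lengths 60-200, power-law leaf prevalence), and a
#' train/validation/test split. The train:validation ratio within the
#' modelling set is 80:20, with an extra held-out test fraction.
#'
#' @param n cohort size (default 500).
#' @param seed single seed for every random choice (default 7).
#' @param nTerms,maxDepth ontology size (defaults 40 and 6).
#' @param fractions three-way split (default 0.64/0.16/0.20).
#' @param ... passed to [generateCohort()].
#' @return list with `records`, `graph` (levels assigned), `annotations`
#'   (direct truth), `truth` (propagated), `split`, `params`.
#' @export
generateBenchmark <- function(n = 500, seed = 7L, nTerms = 40,
                              maxDepth = 6,
                              fractions = c(train = 0.64,
                                            validation = 0.16,
                                            test = 0.20), ...) {
  graph <- assignLevels(generateToyOntology(nTerms, maxDepth,
                                            seed = seed))
  cohort <- generateCohort(n, graph, seed = seed + 1L, ...)
  split <- splitCohort(vapply(cohort$records, `[[`, "", "id"),
                       fractions, seed = seed + 2L)
  truth <- propagateAnnotations(cohort$annotations, graph)
  list(records = cohort$records, graph = graph,
       annotations = cohort$annotations, truth = truth, split = split,
       motifTable = cohort$motifTable,
       params = list(n = n, seed = seed, nTerms = nTerms,
                     maxDepth = maxDepth, fractions = fractions))
}
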