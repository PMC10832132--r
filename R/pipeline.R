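#' Binary label matrix from an annotation table
#'
#' @param tab a propagated [AnnotationTable-class].
#' @param labelSpace a [LabelSpace-class].
#' @param proteinIds column order of the result.
#' @return binary matrix, labels x proteins, with dimnames.
#' @export
labelMatrix <- function(tab, labelSpace, proteinIds) {
  stopifnot(is(tab, "AnnotationTable"))
  terms <- labelSpace@table$term
  Y <- matrix(0, length(terms), length(proteinIds),
              dimnames = list(terms, proteinIds))
  keep <- tab@pairs$term %in% terms & tab@pairs$protein %in% proteinIds
  if (any(keep))
    Y[cbind(tab@pairs$term[keep], tab@pairs$protein[keep])] <- 1
  Y
}

# flattened feature-map images for a normalized cohort matrix
.promapBatch <- function(dm, map) {
  S <- map@gridSide
  nc <- length(map@spec$classes)
  out <- matrix(0, nc * S * S, nrow(dm@values))
  for (i in seq_len(nrow(dm@values)))
    out[, i] <- as.numeric(makeProMap(dm@values[i, ], map,
                                      normalized = TRUE))
  out
}

#' Train the full annotation model on a cohort
#'
#' End-to-end training: propagates annotations, selects the label space,
#' computes and normalizes descriptors, freezes the template map, renders
#' feature-map images and similarity vectors, pre-trains the dual-path
#' encoder, trains the LSTM decoder on the frozen embeddings, and selects
#' the ensemble weight against the similarity-transfer baseline on the
#' validation split (80/20 by default).
#'
#' @param records list of protein records (training cohort; also the
#'   similarity reference for later queries).
#' @param annotations an [AnnotationTable-class] (propagated or not).
#' @param graph a [GeneOntologyGraph-class].
#' @param config a [runConfig()].
#' @param split optional named list with integer indices `train` and
#'   `validation`; by default an 80/20 split drawn with `config$seed`.
#' @param verbose print training progress.
#' @return A [ProFunModel-class]; training histories and the split are
#'   attached as attributes `history` and `split`.
#' @export
trainProFunModel <- function(records, annotations, graph,
                             config = runConfig(), split = NULL,
                             verbose = FALSE) {
  if (!length(graph@level)) graph <- assignLevels(graph)
  prop <- if (isTRUE(annotations@propagated)) annotations else
    propagateAnnotations(annotations, graph)
  labels <- selectLabelFamilies(prop, graph,
                                minCount = config$familyMinCount,
                                anpCutoff = config$anpCutoff)
  ids <- vapply(records, `[[`, "", "id")
  dm <- normalizeDescriptorMatrix(
    computeDescriptorMatrix(records, config$spec))
  if (is.null(split)) {
    sp <- splitCohort(ids, c(train = 0.8, validation = 0.2),
                      seed = config$seed)
    split <- list(train = which(sp == "train"),
                  validation = which(sp == "validation"))
  }
  map <- buildTemplateMap(dm, method = config$reduction,
                          seed = config$seed, gridSide = config$gridSide)
  pdm <- proteinDistanceMatrix(dm)
  promaps <- .promapBatch(dm, map)
  Y <- labelMatrix(prop, labels, ids)
  mc <- config$model
  encoder <- buildEncoder(mc, nrow(labels@table),
                          nChannels = length(map@spec$classes),
                          gridSideLen = map@gridSide, nRef = length(ids))
  pre <- pretrainEncoder(encoder, promaps, pdm, Y, mc,
                         trainIdx = split$train, valIdx = split$validation,
                         verbose = verbose)
  chunks <- chunkLabelsByLevel(labels, mc$timeSteps)
  decTr <- trainDecoder(pre$embeddings, Y, chunks, mc,
                        trainIdx = split$train, valIdx = split$validation,
                        verbose = verbose)
  k <- min(mc$ensembleK, length(split$train))
  dlVal <- decoderScores(decTr$decoder,
                         pre$embeddings[, split$validation, drop = FALSE])
  simVal <- similarityTransfer(
    pdm[split$train, split$validation, drop = FALSE],
    Y[, split$train, drop = FALSE], k = k)
  truthVal <- apply(Y[, split$validation, drop = FALSE] > 0, 2, which,
                    simplify = FALSE)
  sel <- selectEnsembleAlpha(dlVal, simVal, truthVal)
  model <- new("ProFunModel", map = map, reference = dm,
               refAnnotations = prop, labels = labels, graph = graph,
               encoder = pre$encoder, decoder = decTr$decoder,
               alpha = sel$alpha,
               config = c(mc, list(reduction = config$reduction,
                                   ensembleKUsed = k)))
  attr(model, "history") <- list(encoder = pre$history,
                                 decoder = decTr$history,
                                 valFmax = sel$fmax)
  attr(model, "split") <- split
  model
}

#' Predict GO annotations for query sequences
#'
#' Runs the frozen pipeline end to end on new sequences: descriptor
#' computation, normalization against the stored reference statistics,
#' feature-map rendering, similarity-vector computation against the
#' reference cohort, encoder and decoder forward passes, ensembling with
#' similarity transfer, and (by default) hierarchical score consistency --
#' each term's score is raised to the maximum over its descendants, so a
#' parent never scores below a child.
#'
#' @param model a [ProFunModel-class].
#' @param queries list of records (`id`, `sequence`) or a FASTA path.
#' @return numeric matrix of scores in [0,1], proteins x label terms.
#' @export
predictFunctions <- function(model, queries) {
  if (is.character(queries) && length(queries) == 1)
    queries <- readFasta(queries)
  terms <- model@labels@table$term
  if (!length(queries)) {
    warning("no query sequences; returning an empty prediction matrix")
    return(matrix(0, 0, length(terms),
                  dimnames = list(character(0), terms)))
  }
  ids <- vapply(queries, `[[`, "", "id")
  ref <- model@reference
  spec <- model@map@spec
  desc <- t(vapply(queries, function(r)
    assembleDescriptorVector(r$sequence, spec), numeric(spec$total)))
  vals <- .normalizeWith(desc, model@map@featMin, model@map@featMax)
  qdm <- new("DescriptorMatrix", values = vals, proteinIds = ids,
             spec = spec, featMin = model@map@featMin,
             featMax = model@map@featMax, normalized = TRUE)
  promaps <- .promapBatch(qdm, model@map)
  prosims <- vapply(seq_along(queries), function(i)
    makeProSim(desc[i, ], ref), numeric(nrow(ref@values)))
  emb <- matrix(0, 2 * model@encoder$geom$E, length(queries))
  for (b in .minibatches(seq_along(queries), 256L))
    emb[, b] <- .encoderForward(model@encoder,
                                promaps[, b, drop = FALSE],
                                prosims[, b, drop = FALSE],
                                needCache = FALSE)$embedding
  dl <- decoderScores(model@decoder, emb)
  Yref <- labelMatrix(model@refAnnotations, model@labels, ref@proteinIds)
  k <- min(model@config$ensembleKUsed %||% model@config$ensembleK,
           nrow(ref@values))
  sim <- similarityTransfer(prosims, Yref, k = k)
  scores <- ensembleCombine(dl, sim, model@alpha)
  if (isTRUE(model@config$hierConsistency))
    scores <- .hierarchicalMax(scores, model@labels, model@graph)
  scores <- pmin(pmax(scores, 0), 1)
  dimnames(scores) <- list(terms, ids)
  t(scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn predictFunctions S4 predict method.
#' @param object a [ProFunModel-class].
#' @param ... passed on (`queries`).
#' @export
setMethod("predict", "ProFunModel", function(object, ...)
  predictFunctions(object, ...))
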