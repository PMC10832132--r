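#' @useDynLib ProFunMap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Cohort-by-feature descriptor matrix
#'
#' Holds the protein-descriptor matrix: one row per protein, one column per
#' sequence descriptor, together with the descriptor specification that
#' produced it and, after normalization, the per-feature minimum and maximum
#' used for the min-max rescaling so that query proteins can be normalized
#' against the same reference statistics.
#'
#' @slot values numeric matrix, proteins x features.
#' @slot proteinIds character, unique protein identifiers (row order).
#' @slot spec list, the descriptor specification (see
#'   [defaultDescriptorSpec()]).
#' @slot featMin,featMax numeric, per-feature reference minima/maxima
#'   (length 0 before normalization).
#' @slot normalized logical scalar.
#' @exportClass DescriptorMatrix
setClass("DescriptorMatrix",
  representation(
    values = "matrix",
    proteinIds = "character",
    spec = "list",
    featMin = "numeric",
    featMax = "numeric",
    normalized = "logical"
  )
)

setValidity("DescriptorMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@proteinIds))
    msg <- c(msg, "number of rows must equal number of protein ids")
  if (anyDuplicated(object@proteinIds))
    msg <- c(msg, "protein ids must be unique")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "descriptor values must be finite")
  if (isTRUE(object@normalized)) {
    if (length(object@featMin) != ncol(object@values) ||
        length(object@featMax) != ncol(object@values))
      msg <- c(msg, "normalized matrix must store per-feature min and max")
    rng <- range(object@values)
    if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
      msg <- c(msg, "normalized values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Frozen feature-to-grid template map
#'
#' The cohort-level layout shared by all feature-map images: an injective
#' assignment of descriptor indices to cells of a square grid, obtained by
#' embedding the feature-distance matrix in 2-D and solving the linear
#' assignment of embedded points to grid-cell centers. The map also carries
#' the reference normalization statistics so that any protein can be rendered
#' with the same intensities.
#'
#' @slot gridSide integer, side length of the square grid.
#' @slot assignment integer, feature index -> 1-based grid cell (row-major);
#'   injective.
#' @slot embedding numeric matrix, features x 2 (the 2-D coordinates before
#'   assignment).
#' @slot method character, dimensionality-reduction method ("pca" or "umap").
#' @slot seed integer, seed used for the reduction.
#' @slot spec list, descriptor specification (defines the channel order).
#' @slot featMin,featMax numeric, reference normalization statistics.
#' @exportClass TemplateMap
setClass("TemplateMap",
  representation(
    gridSide = "integer",
    assignment = "integer",
    embedding = "matrix",
    method = "character",
    seed = "integer",
    spec = "list",
    featMin = "numeric",
    featMax = "numeric"
  )
)

setValidity("TemplateMap", function(object) {
  msg <- character()
  n <- length(object@assignment)
  if (object@gridSide^2 < n)
    msg <- c(msg, "gridSide^2 must be >= number of features")
  if (anyDuplicated(object@assignment))
    msg <- c(msg, "assignment must be injective")
  if (n && (min(object@assignment) < 1 ||
            max(object@assignment) > object@gridSide^2))
    msg <- c(msg, "assigned cells out of grid range")
  if (nrow(object@embedding) != n)
    msg <- c(msg, "embedding must have one row per feature")
  if (length(msg)) msg else TRUE
})

#' Gene Ontology DAG with hierarchy levels
#'
#' A parsed is_a ontology: terms with namespaces, child-to-parent edges, one
#' root per namespace, and (after [assignLevels()]) a hierarchy level per
#' term with roots at level 1 and each term one step below its shallowest
#' parent.
#'
#' @slot terms data.frame with columns id, name, namespace.
#' @slot parents named list, term id -> character vector of parent ids.
#' @slot roots named character, namespace -> root term id.
#' @slot level named integer, term id -> level (length 0 before
#'   [assignLevels()]).
#' @exportClass GeneOntologyGraph
setClass("GeneOntologyGraph",
  representation(
    terms = "data.frame",
    parents = "list",
    roots = "character",
    level = "integer"
  )
)

setValidity("GeneOntologyGraph", function(object) {
  msg <- character()
  if (!all(c("id", "name", "namespace") %in% names(object@terms)))
    msg <- c(msg, "terms needs columns id, name, namespace")
  if (anyDuplicated(object@terms$id))
    msg <- c(msg, "term ids must be unique")
  bad <- setdiff(unlist(object@parents, use.names = FALSE), object@terms$id)
  if (length(bad))
    msg <- c(msg, paste0("unknown parent term(s): ",
                         paste(utils::head(bad, 3), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Protein-to-term annotation table
#'
#' @slot pairs data.frame with columns protein, term (unique rows).
#' @slot propagated logical; TRUE once closed under the true-path rule
#'   (annotation to a term implies annotation to all its non-root ancestors).
#' @exportClass AnnotationTable
setClass("AnnotationTable",
  representation(pairs = "data.frame", propagated = "logical")
)

setValidity("AnnotationTable", function(object) {
  msg <- character()
  if (!all(c("protein", "term") %in% names(object@pairs)))
    msg <- c(msg, "pairs needs columns protein, term")
  if (anyDuplicated(object@pairs))
    msg <- c(msg, "annotation pairs must be unique")
  if (length(msg)) msg else TRUE
})

#' Selected label space for model training
#'
#' GO terms retained for prediction: families with more than the configured
#' minimum number of annotated proteins (roots excluded), ordered by level
#' and then term id so the ordering is stable across runs.
#'
#' @slot table data.frame with columns term, namespace, level, count, head
#'   (logical: does the term's level average >= the head/tail cutoff).
#' @slot minCount integer, strict lower bound used for selection.
#' @slot anpCutoff numeric, head/tail average-protein-count cutoff.
#' @exportClass LabelSpace
setClass("LabelSpace",
  representation(table = "data.frame", minCount = "integer",
                 anpCutoff = "numeric")
)

setValidity("LabelSpace", function(object) {
  msg <- character()
  need <- c("term", "namespace", "level", "count", "head")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table needs columns", paste(need, collapse = ", ")))
  if (anyDuplicated(object@table$term))
    msg <- c(msg, "label terms must be unique")
  ord <- order(object@table$level, object@table$term)
  if (nrow(object@table) && !identical(ord, seq_len(nrow(object@table))))
    msg <- c(msg, "labels must be ordered by level then term id")
  if (length(msg)) msg else TRUE
})

#' Trained annotation model bundle
#'
#' Everything needed for end-to-end prediction on new sequences: descriptor
#' spec, frozen template map (with normalization statistics), normalized
#' reference descriptor matrix and propagated reference annotations, label
#' space, ontology, trained dual-path encoder and LSTM decoder weights, the
#' ensemble mixing weight, and the resolved model configuration.
#'
#' @slot map a [TemplateMap-class].
#' @slot reference a normalized [DescriptorMatrix-class] (training cohort).
#' @slot refAnnotations a propagated [AnnotationTable-class].
#' @slot labels a [LabelSpace-class].
#' @slot graph a [GeneOntologyGraph-class] with levels.
#' @slot encoder,decoder lists of trained weight arrays plus geometry.
#' @slot alpha numeric in [0,1], weight of the deep-learning scores in the
#'   ensemble with similarity transfer.
#' @slot config list, resolved [modelConfig()].
#' @exportClass ProFunModel
setClass("ProFunModel",
  representation(
    map = "TemplateMap",
    reference = "DescriptorMatrix",
    refAnnotations = "AnnotationTable",
    labels = "LabelSpace",
    graph = "GeneOntologyGraph",
    encoder = "list",
    decoder = "list",
    alpha = "numeric",
    config = "list"
  )
)

setValidity("ProFunModel", function(object) {
  if (length(object@alpha) != 1 || object@alpha < 0 || object@alpha > 1)
    return("alpha must be a single value in [0, 1]")
  TRUE
})
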