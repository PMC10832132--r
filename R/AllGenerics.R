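#' Accessors for ProFunMap classes
#'
#' Small accessor generics: `proteinIds()` returns the protein identifiers
#' of a descriptor matrix, `descriptorValues()` its numeric matrix,
#' `gridSide()` and `mapAssignment()` the geometry of a template map,
#' `goLevels()` and `goRoots()` the level map and namespace roots of an
#' ontology, `annotationPairs()` the protein/term pair table, and
#' `labelTerms()` the ordered term vector of a label space.
#'
#' @param x an object of the documented class.
#' @return See each method's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))
#' @rdname accessors
#' @export
setGeneric("gridSide", function(x) standardGeneric("gridSide"))
#' @rdname accessors
#' @export
setGeneric("mapAssignment", function(x) standardGeneric("mapAssignment"))
#' @rdname accessors
#' @export
setGeneric("goLevels", function(x) standardGeneric("goLevels"))
#' @rdname accessors
#' @export
setGeneric("goRoots", function(x) standardGeneric("goRoots"))
#' @rdname accessors
#' @export
setGeneric("annotationPairs", function(x) standardGeneric("annotationPairs"))
#' @rdname accessors
#' @export
setGeneric("labelTerms", function(x) standardGeneric("labelTerms"))

#' @rdname accessors
setMethod("proteinIds", "DescriptorMatrix", function(x) x@proteinIds)
#' @rdname accessors
setMethod("descriptorValues", "DescriptorMatrix", function(x) x@values)
#' @rdname accessors
setMethod("gridSide", "TemplateMap", function(x) x@gridSide)
#' @rdname accessors
setMethod("mapAssignment", "TemplateMap", function(x) x@assignment)
#' @rdname accessors
setMethod("goLevels", "GeneOntologyGraph", function(x) x@level)
#' @rdname accessors
setMethod("goRoots", "GeneOntologyGraph", function(x) x@roots)
#' @rdname accessors
setMethod("annotationPairs", "AnnotationTable", function(x) x@pairs)
#' @rdname accessors
setMethod("labelTerms", "LabelSpace", function(x) x@table$term)

setMethod("show", "DescriptorMatrix", function(object) {
  cat(sprintf("DescriptorMatrix: %d proteins x %d features (%s)\n",
              nrow(object@values), ncol(object@values),
              if (isTRUE(object@normalized)) "normalized to [0,1]"
              else "raw"))
  cls <- vapply(object@spec$classes, function(cl) {
    sprintf("%s[%d]", cl$name, cl$length)
  }, character(1))
  cat("  classes:", paste(cls, collapse = " + "), "\n")
})

setMethod("show", "TemplateMap", function(object) {
  cat(sprintf(
    "TemplateMap: %d features on a %d x %d grid (%d empty cells)\n",
    length(object@assignment), object@gridSide, object@gridSide,
    object@gridSide^2 - length(object@assignment)))
  cat(sprintf("  reduction: %s (seed %d)\n", object@method, object@seed))
})

setMethod("show", "GeneOntologyGraph", function(object) {
  cat(sprintf("GeneOntologyGraph: %d terms, %d namespaces\n",
              nrow(object@terms), length(object@roots)))
  if (length(object@level))
    cat(sprintf("  levels assigned: 1..%d\n", max(object@level)))
})

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf("AnnotationTable: %d pairs, %d proteins, %d terms (%s)\n",
              nrow(object@pairs), length(unique(object@pairs$protein)),
              length(unique(object@pairs$term)),
              if (isTRUE(object@propagated)) "propagated" else "direct"))
})

setMethod("show", "LabelSpace", function(object) {
  tb <- object@table
  cat(sprintf(
    "LabelSpace: %d families (count > %d), levels %s\n",
    nrow(tb), object@minCount,
    if (nrow(tb)) paste(range(tb$level), collapse = "..") else "-"))
  if (nrow(tb))
    cat(sprintf("  head levels (ANP >= %g): %d terms; tail: %d terms\n",
                object@anpCutoff, sum(tb$head), sum(!tb$head)))
})

setMethod("show", "ProFunModel", function(object) {
  cat(sprintf(
    "ProFunModel: %d reference proteins, %d GO families, alpha = %.2f\n",
    nrow(object@reference@values), nrow(object@labels@table), object@alpha))
  cat(sprintf("  grid %d x %d, %d channels, %d decoder time steps\n",
              object@map@gridSide, object@map@gridSide,
              length(object@map@spec$classes), object@config$timeSteps))
})
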