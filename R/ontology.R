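#' Parse an OBO 1.2 ontology
#'
#' Reads `[Term]` stanzas, keeping id, name, namespace and `is_a` edges
#' only (`part_of`/`regulates` relationships are dropped so each namespace
#' forms a single-rooted DAG). Obsolete terms are excluded with a message.
#' A term with no parents is taken as the root of its namespace; each
#' namespace must have exactly one root. Cycles raise an error naming a
#' member term.
#'
#' @param path OBO file path.
#' @return A [GeneOntologyGraph-class] (levels not yet assigned).
#' @export
parseOBO <- function(path) {
  if (!file.exists(path)) stop("input-not-found: ", path)
  lines <- readLines(path)
  starts <- c(grep("^\\[", lines), length(lines) + 1L)
  termStarts <- grep("^\\[Term\\]$", lines)
  ids <- names <- nss <- character(0)
  parents <- list()
  nObsolete <- 0L
  for (s in termStarts) {
    e <- min(starts[starts > s]) - 1L
    block <- lines[s:e]
    field <- function(key) sub(paste0("^", key, ": "), "",
                               grep(paste0("^", key, ": "), block,
                                    value = TRUE))
    if (any(grepl("^is_obsolete: true", block))) {
      nObsolete <- nObsolete + 1L
      next
    }
    id <- field("id")[1]
    if (is.na(id)) next
    ids <- c(ids, id)
    nm <- field("name")
    names <- c(names, if (length(nm)) nm[1] else id)
    ns <- field("namespace")
    nss <- c(nss, if (length(ns)) ns[1] else "default")
    isa <- field("is_a")
    parents[[id]] <- sub("\\s*!.*$", "", isa)
  }
  if (nObsolete) message(nObsolete, " obsolete term(s) dropped")
  if (!length(ids)) stop("no terms found in ", path)
  # drop is_a references to terms that were excluded (e.g. obsolete)
  parents <- lapply(parents, function(p) intersect(p, ids))
  terms <- data.frame(id = ids, name = names, namespace = nss)
  g <- igraph::graph_from_data_frame(
    d = if (sum(lengths(parents)))
      data.frame(from = rep(ids, lengths(parents[ids])),
                 to = unlist(parents[ids], use.names = FALSE)) else
      data.frame(from = character(), to = character()),
    vertices = terms$id, directed = TRUE)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    if (!length(bad))
      bad <- unique(igraph::as_ids(igraph::E(g)[igraph::which_loop(g)]))
    stop("ontology contains a cycle involving term: ", bad[1])
  }
  roots <- character(0)
  for (ns in unique(nss)) {
    inNs <- ids[nss == ns]
    r <- inNs[lengths(parents[inNs]) == 0]
    if (length(r) != 1)
      stop("namespace '", ns, "' must have exactly one root, found ",
           length(r))
    roots[ns] <- r
  }
  new("GeneOntologyGraph", terms = terms, parents = parents,
      roots = roots, level = integer(0))
}

#' Assign hierarchy levels to ontology terms
#'
#' Roots sit at level 1; every other term is one level below its
#' shallowest parent (`level = 1 + min over parents`), i.e. the
#' shortest-path depth from the namespace root plus one. Terms that cannot
#' reach a root raise an error.
#'
#' @param graph a [GeneOntologyGraph-class].
#' @return The graph with its `level` slot filled.
#' @export
assignLevels <- function(graph) {
  stopifnot(is(graph, "GeneOntologyGraph"))
  ids <- graph@terms$id
  level <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  level[graph@roots] <- 1L
  frontier <- unname(graph@roots)
  children <- .childrenIndex(graph)
  cur <- 1L
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(children[frontier], use.names = FALSE)),
                   names(level)[!is.na(level)])
    level[nxt] <- cur + 1L
    frontier <- nxt
    cur <- cur + 1L
  }
  if (anyNA(level))
    stop("term(s) unreachable from any root: ",
         paste(utils::head(ids[is.na(level[ids])], 5), collapse = ", "))
  graph@level <- level
  graph
}

.childrenIndex <- function(graph) {
  ids <- graph@terms$id
  kids <- stats::setNames(vector("list", length(ids)), ids)
  for (t in ids) for (p in graph@parents[[t]])
    kids[[p]] <- c(kids[[p]], t)
  kids
}

# all ancestors of each term up to and excluding the roots, memoized
.ancestorIndex <- function(graph, excludeRoots = TRUE) {
  ids <- graph@terms$id
  anc <- stats::setNames(vector("list", length(ids)), ids)
  done <- stats::setNames(logical(length(ids)), ids)
  getAnc <- function(t) {
    if (done[[t]]) return(anc[[t]])
    ps <- graph@parents[[t]]
    res <- unique(c(ps, unlist(lapply(ps, getAnc), use.names = FALSE)))
    anc[[t]] <<- res
    done[[t]] <<- TRUE
    res
  }
  for (t in ids) getAnc(t)
  if (excludeRoots)
    anc <- lapply(anc, function(a) setdiff(a, graph@roots))
  anc
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Every (protein, term) pair implies (protein, ancestor) for all ancestors
#' of the term up to, and excluding, the namespace roots. Idempotent.
#'
#' @param tab an [AnnotationTable-class].
#' @param graph a [GeneOntologyGraph-class].
#' @return A propagated [AnnotationTable-class].
#' @export
propagateAnnotations <- function(tab, graph) {
  stopifnot(is(tab, "AnnotationTable"), is(graph, "GeneOntologyGraph"))
  anc <- .ancestorIndex(graph, excludeRoots = TRUE)
  pairs <- tab@pairs
  extra <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- anc[[pairs$term[i]]]
    if (length(a)) data.frame(protein = pairs$protein[i], term = a) else NULL
  })
  all <- unique(rbind(pairs, do.call(rbind, extra)))
  # annotations directly on a root are uninformative and dropped
  all <- all[!(all$term %in% graph@roots), , drop = FALSE]
  all <- all[order(all$protein, all$term), , drop = FALSE]
  rownames(all) <- NULL
  new("AnnotationTable", pairs = all, propagated = TRUE)
}

#' Select the label families for model training
#'
#' Keeps GO terms annotated to strictly more than `minCount` proteins
#' (after propagation); roots are excluded. The label table is ordered by
#' level and then term id, and each term carries the head/tail flag of its
#' level (level average protein count >= `anpCutoff` means head).
#'
#' @param tab a propagated [AnnotationTable-class].
#' @param graph a [GeneOntologyGraph-class] with levels assigned.
#' @param minCount strict lower bound on family size (default 50).
#' @param anpCutoff head/tail cutoff on the level's average protein count
#'   (default 2000, inclusive on the head side).
#' @return A [LabelSpace-class].
#' @export
selectLabelFamilies <- function(tab, graph, minCount = 50,
                                anpCutoff = 2000) {
  stopifnot(is(tab, "AnnotationTable"))
  if (!isTRUE(tab@propagated))
    stop("propagate the annotation table first")
  if (!length(graph@level)) stop("assign levels first")
  counts <- table(tab@pairs$term)
  keep <- names(counts)[counts > minCount]
  keep <- setdiff(keep, graph@roots)
  if (!length(keep))
    stop("no family has more than ", minCount,
         " proteins; lower minCount for small cohorts")
  anp <- anpPerLevel(tab, graph)
  headMap <- classifyHeadTail(anp, cutoff = anpCutoff)
  ns <- stats::setNames(graph@terms$namespace, graph@terms$id)
  tabOut <- data.frame(term = keep,
                       namespace = unname(ns[keep]),
                       level = unname(graph@level[keep]),
                       count = as.integer(counts[keep]))
  tabOut$head <- unname(headMap[as.character(tabOut$level)] == "head")
  tabOut <- tabOut[order(tabOut$level, tabOut$term), , drop = FALSE]
  rownames(tabOut) <- NULL
  new("LabelSpace", table = tabOut, minCount = as.integer(minCount),
      anpCutoff = anpCutoff)
}

#' Average number of proteins per ontology level
#'
#' Arithmetic mean of per-family protein counts within each level (only
#' annotated, non-root families contribute; levels without any annotated
#' family are omitted).
#'
#' @param tab a propagated [AnnotationTable-class].
#' @param graph a [GeneOntologyGraph-class] with levels.
#' @return named numeric vector, level -> average protein count.
#' @export
anpPerLevel <- function(tab, graph) {
  stopifnot(is(tab, "AnnotationTable"))
  if (!isTRUE(tab@propagated))
    stop("propagate the annotation table first")
  if (!length(graph@level)) stop("assign levels first")
  counts <- table(tab@pairs$term)
  terms <- setdiff(names(counts), graph@roots)
  if (!length(terms)) return(stats::setNames(numeric(0), character(0)))
  lv <- graph@level[terms]
  out <- tapply(as.integer(counts[terms]), lv, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Classify ontology levels as head or tail
#'
#' A level is a head label level when its average protein count is at least
#' the cutoff (inclusive), otherwise a tail label level.
#'
#' @param anp named numeric vector from [anpPerLevel()].
#' @param cutoff average-protein-count boundary (default 2000).
#' @return named character vector, level -> "head" or "tail".
#' @export
classifyHeadTail <- function(anp, cutoff = 2000) {
  stats::setNames(ifelse(anp >= cutoff, "head", "tail"), names(anp))
}
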