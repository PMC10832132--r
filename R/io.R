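#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into a list of protein records (id + sequence).
#' Identifiers are taken from the header up to the first whitespace and must
#' be unique. Sequences are sanitized to the 20 canonical residues: by
#' default B is mapped to D, Z to E, J to L, U to C, O to K, and X (or any
#' other unknown letter) is dropped.
#'
#' @param path FASTA file path.
#' @param residuePolicy "map" (default: map ambiguous residues, drop
#'   unknowns) or "drop-residue" (drop every non-canonical residue).
#' @return A list of records, each `list(id =, sequence =)`.
#' @export
readFasta <- function(path, residuePolicy = c("map", "drop-residue")) {
  residuePolicy <- match.arg(residuePolicy)
  if (!file.exists(path)) stop("input-not-found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- sanitizeSequences(as.character(set), policy = residuePolicy)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("sequence(s) empty after sanitization: ",
         paste(ids[empty], collapse = ", "))
  mapply(function(i, s) list(id = i, sequence = s), ids, seqs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Sanitize amino-acid sequences to the canonical 20-letter alphabet
#'
#' @param sequences character vector.
#' @param policy "map" replaces B->D, Z->E, J->L, U->C, O->K and drops X and
#'   anything else; "drop-residue" drops every non-canonical letter.
#' @return character vector of sanitized sequences.
#' @export
sanitizeSequences <- function(sequences, policy = c("map", "drop-residue")) {
  policy <- match.arg(policy)
  up <- toupper(sequences)
  if (policy == "map")
    up <- chartr("BZJUO", "DELCK", up)
  vapply(up, function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(chars[chars %in% .AA], collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records list of records (`id`, `sequence`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path) {
  ids <- vapply(records, `[[`, "", "id")
  seqs <- vapply(records, `[[`, "", "sequence")
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a protein-to-GO annotation table
#'
#' Reads a two-column TSV (protein_id, go_id), de-duplicates pairs, and
#' validates every term against the supplied ontology. Rows whose term is
#' absent from the ontology trigger an error listing the offending terms.
#'
#' @param path TSV path (no header expected; a `protein_id` header row is
#'   tolerated and skipped).
#' @param ontology a [GeneOntologyGraph-class].
#' @return An [AnnotationTable-class] with `propagated = FALSE`.
#' @export
readAnnotations <- function(path, ontology) {
  if (!file.exists(path)) stop("input-not-found: ", path)
  lines <- readLines(path)
  if (length(lines) && grepl("^protein_id\\b", lines[1]))
    lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty annotation file: ", path)
    return(new("AnnotationTable",
               pairs = data.frame(protein = character(),
                                  term = character()),
               propagated = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop("malformed annotation row at line ", bad[1], ": expected 2 ",
         "tab-separated fields, got ", length(parts[[bad[1]]]))
  pairs <- unique(data.frame(protein = vapply(parts, `[`, "", 1),
                             term = vapply(parts, `[`, "", 2)))
  unknown <- setdiff(pairs$term, ontology@terms$id)
  if (length(unknown))
    stop("annotation term(s) absent from ontology: ",
         paste(unknown, collapse = ", "))
  rownames(pairs) <- NULL
  new("AnnotationTable", pairs = pairs, propagated = FALSE)
}

#' Write a prediction matrix as TSV
#'
#' Writes rows (protein_id, go_id, score) with scores rounded to
#' `digits` decimals, sorted by protein id and then by descending score
#' (ties by term id). Re-reading with [readPredictions()] reproduces the
#' written scores exactly at the stated precision.
#'
#' @param scores numeric matrix in [0,1], proteins x terms, with dimnames.
#' @param path output TSV path.
#' @param digits decimals kept in the output (default 3).
#' @param minScore rounded scores strictly below this are omitted
#'   (default -1: keep everything).
#' @return `path`, invisibly.
#' @export
writePredictions <- function(scores, path, digits = 3, minScore = -1) {
  if (is.null(colnames(scores)) ||
      (nrow(scores) > 0 && is.null(rownames(scores))))
    stop("prediction matrix needs protein and term dimnames")
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    stop("prediction scores must lie in [0, 1]")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("protein_id\tgo_id\tscore", con)
  for (i in seq_len(nrow(scores))) {
    s <- round(scores[i, ], digits)
    keep <- which(s >= minScore)
    if (!length(keep)) next
    ord <- keep[order(-s[keep], colnames(scores)[keep])]
    writeLines(sprintf(paste0("%s\t%s\t%.", digits, "f"),
                       rownames(scores)[i], colnames(scores)[ord], s[ord]),
               con)
  }
  invisible(path)
}

#' Read a prediction TSV back into a matrix
#'
#' @param path TSV written by [writePredictions()].
#' @return numeric matrix, proteins x terms (absent pairs are 0).
#' @export
readPredictions <- function(path) {
  if (!file.exists(path)) stop("input-not-found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "numeric"))
  prot <- unique(df$protein_id)
  term <- sort(unique(df$go_id))
  m <- matrix(0, length(prot), length(term),
              dimnames = list(prot, term))
  if (nrow(df)) m[cbind(df$protein_id, df$go_id)] <- df$score
  m
}

#' Default run configuration
#'
#' Gathers every tunable of the pipeline with its default: the descriptor
#' spec, the reduction method ("pca" or "umap"), an optional grid-side
#' override, the model hyperparameters (see [modelConfig()]), the random
#' seed, and the selection thresholds (strict family minimum 50; head/tail
#' average-protein-count cutoff 2,000, inclusive).
#'
#' @param ... overrides for any top-level field.
#' @return A named list.
#' @export
runConfig <- function(...) {
  cfg <- list(
    spec = defaultDescriptorSpec(),
    reduction = "pca",
    gridSide = NULL,
    model = modelConfig(),
    seed = 1L,
    familyMinCount = 50L,
    anpCutoff = 2000
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}
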