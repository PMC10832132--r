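#' Min-max normalize a descriptor matrix
#'
#' Rescales every feature to [0,1] across the cohort:
#' `x_norm = (x - min_f) / (max_f - min_f)` with the per-feature minimum and
#' maximum taken over all proteins. Constant features are set to 0 with a
#' warning. The min/max are stored on the object so query proteins can be
#' normalized against the same reference statistics.
#'
#' @param dm an unnormalized [DescriptorMatrix-class] with >= 2 proteins.
#' @return A normalized [DescriptorMatrix-class].
#' @export
normalizeDescriptorMatrix <- function(dm) {
  stopifnot(is(dm, "DescriptorMatrix"))
  if (isTRUE(dm@normalized)) return(dm)
  if (nrow(dm@values) < 2) stop("normalization needs at least 2 proteins")
  if (any(!is.finite(dm@values))) stop("non-finite descriptor values")
  mins <- unname(apply(dm@values, 2, min))
  maxs <- unname(apply(dm@values, 2, max))
  const <- maxs == mins
  if (any(const))
    warning(sum(const), " constant feature(s) set to 0 after normalization")
  rng <- maxs - mins
  rng[const] <- 1
  vals <- sweep(sweep(dm@values, 2, mins), 2, rng, "/")
  vals[, const] <- 0
  new("DescriptorMatrix", values = vals, proteinIds = dm@proteinIds,
      spec = dm@spec, featMin = mins, featMax = maxs, normalized = TRUE)
}

# normalize query descriptor rows with frozen reference statistics,
# clipping to [0,1]
.normalizeWith <- function(values, featMin, featMax) {
  rng <- featMax - featMin
  const <- rng == 0
  rng[const] <- 1
  vals <- sweep(sweep(values, 2, featMin), 2, rng, "/")
  vals[, const] <- 0
  pmin(pmax(vals, 0), 1)
}

# cosine distance 1 - <a,b>/(|a||b|) between all column pairs of M;
# zero-norm vectors get distance 1 to everything (no similarity signal)
.cosineDistance <- function(M) {
  nrm <- sqrt(colSums(M^2))
  zero <- nrm == 0
  if (any(zero)) {
    message(sum(zero), " zero-norm vector(s): cosine distance set to 1")
    nrm[zero] <- 1
  }
  Mn <- sweep(M, 2, nrm, "/")
  d <- 1 - crossprod(Mn)
  d[zero, ] <- 1
  d[, zero] <- 1
  diag(d) <- 0
  d <- (d + t(d)) / 2
  pmin(pmax(d, 0), 2)
}

#' Pairwise cosine distances among features
#'
#' Each feature is viewed as a vector of length n_proteins over the
#' normalized cohort matrix; the distance is `1 - cos(f_a, f_b)`, in [0,2],
#' symmetric with a zero diagonal.
#'
#' @param dm a normalized [DescriptorMatrix-class].
#' @return numeric matrix, features x features.
#' @export
featureDistanceMatrix <- function(dm) {
  stopifnot(is(dm, "DescriptorMatrix"))
  if (!isTRUE(dm@normalized)) stop("normalize the matrix first")
  .cosineDistance(dm@values)
}

#' Pairwise cosine distances among proteins
#'
#' Same cosine distance applied to matrix rows (proteins as vectors of
#' length n_features).
#'
#' @param dm a normalized [DescriptorMatrix-class].
#' @return numeric matrix, proteins x proteins, with protein-id dimnames.
#' @export
proteinDistanceMatrix <- function(dm) {
  stopifnot(is(dm, "DescriptorMatrix"))
  if (!isTRUE(dm@normalized)) stop("normalize the matrix first")
  d <- .cosineDistance(t(dm@values))
  dimnames(d) <- list(dm@proteinIds, dm@proteinIds)
  d
}

#' Embed the feature-distance matrix in 2-D
#'
#' `method = "pca"` runs a principal component analysis on the rows of the
#' distance matrix (each feature represented by its vector of distances to
#' all features) and keeps the first two components. `method = "umap"`
#' delegates to the python `umap-learn` package (metric = "precomputed",
#' `random_state = seed`) through a subprocess; it requires `python` with
#' umap-learn on the PATH.
#'
#' @param fdm square feature-distance matrix.
#' @param method "pca" or "umap".
#' @param seed integer seed (fixed for reproducibility).
#' @param nNeighbors,minDist UMAP parameters (defaults 15 and 0.1).
#' @return numeric matrix, features x 2.
#' @export
reduceTo2D <- function(fdm, method = c("pca", "umap"), seed = 1L,
                       nNeighbors = 15, minDist = 0.1) {
  method <- match.arg(method)
  if (nrow(fdm) != ncol(fdm)) stop("distance matrix must be square")
  if (method == "pca") {
    set.seed(seed)
    pc <- stats::prcomp(fdm, center = TRUE, scale. = FALSE, rank. = 2)
    emb <- pc$x[, 1:2, drop = FALSE]
    # sign convention: largest-|loading| coordinate positive, so the
    # embedding is reproducible across BLAS implementations
    for (k in 1:2) {
      j <- which.max(abs(pc$rotation[, k]))
      if (pc$rotation[j, k] < 0) emb[, k] <- -emb[, k]
    }
    dimnames(emb) <- NULL
    return(emb)
  }
  .umapSubprocess(fdm, seed, nNeighbors, minDist)
}

.umapSubprocess <- function(fdm, seed, nNeighbors, minDist) {
  python <- Sys.which("python")
  if (!nzchar(python)) stop("'umap' reduction needs python with umap-learn")
  dir <- tempfile("umap")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  inCsv <- file.path(dir, "d.csv")
  outCsv <- file.path(dir, "emb.csv")
  utils::write.table(fdm, inCsv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- file.path(dir, "run.py")
  writeLines(c(
    "import sys, numpy as np, warnings",
    "warnings.filterwarnings('ignore')",
    "import umap",
    "d = np.loadtxt(sys.argv[1], delimiter=',')",
    sprintf(paste0("m = umap.UMAP(n_components=2, metric='precomputed', ",
                   "n_neighbors=%d, min_dist=%g, random_state=%d)"),
            as.integer(nNeighbors), minDist, as.integer(seed)),
    "np.savetxt(sys.argv[2], m.fit_transform(d), delimiter=',')"
  ), script)
  status <- system2(python, c(script, inCsv, outCsv),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(outCsv))
    stop("umap subprocess failed (exit ", status, ")")
  as.matrix(utils::read.table(outCsv, sep = ","))
}

#' Assign embedded features to distinct grid cells
#'
#' Solves the rectangular linear assignment problem mapping every embedded
#' feature to its own cell of a `gridSide` x `gridSide` grid, minimizing the
#' total squared Euclidean distance between the min-max-rescaled embedding
#' points and the cell centers on the unit square (Jonker-Volgenant). The
#' returned assignment attains the global optimum.
#'
#' @param embedding numeric matrix, features x 2.
#' @param gridSide grid side; default the smallest integer whose square
#'   holds all features.
#' @param method,seed,spec,featMin,featMax metadata stored on the map.
#' @return A [TemplateMap-class].
#' @export
allocateCoordinates <- function(embedding, gridSide = NULL,
                                method = "pca", seed = 1L, spec = list(),
                                featMin = numeric(0),
                                featMax = numeric(0)) {
  n <- nrow(embedding)
  if (is.null(gridSide)) gridSide <- ceiling(sqrt(n))
  gridSide <- as.integer(gridSide)
  if (gridSide^2 < n)
    stop("grid ", gridSide, "x", gridSide, " cannot hold ", n,
         " features; use gridSide >= ", ceiling(sqrt(n)))
  # rescale each embedding axis to [0,1]; degenerate axes collapse to 0.5
  emb01 <- apply(embedding, 2, function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0.5, length(v)) else (v - min(v)) / r
  })
  centers <- cbind(rep((seq_len(gridSide) - 0.5) / gridSide,
                       each = gridSide),
                   rep((seq_len(gridSide) - 0.5) / gridSide,
                       times = gridSide))
  # cost[i, j] = squared distance from feature i to cell j; cells are
  # row-major: cell = (row-1)*gridSide + col, row <-> axis 1
  cost <- outer(emb01[, 1], centers[, 1], "-")^2 +
    outer(emb01[, 2], centers[, 2], "-")^2
  assignment <- lapjv_cpp(cost)
  new("TemplateMap", gridSide = gridSide, assignment = assignment,
      embedding = embedding, method = method, seed = as.integer(seed),
      spec = spec, featMin = featMin, featMax = featMax)
}

#' Build the frozen template map from a reference cohort
#'
#' Composes the whole layout pipeline: descriptor computation (when given
#' FASTA records), min-max normalization, the feature-distance matrix, 2-D
#' reduction and grid assignment. The returned map carries the
#' normalization statistics and seed needed to render any protein.
#'
#' @param x a list of protein records or a [DescriptorMatrix-class].
#' @param spec descriptor specification (ignored when `x` is already a
#'   descriptor matrix).
#' @param method reduction method, "pca" (default) or "umap".
#' @param seed integer seed.
#' @param gridSide optional grid-side override.
#' @return A [TemplateMap-class].
#' @export
buildTemplateMap <- function(x, spec = defaultDescriptorSpec(),
                             method = c("pca", "umap"), seed = 1L,
                             gridSide = NULL) {
  method <- match.arg(method)
  dm <- if (is(x, "DescriptorMatrix")) x else
    computeDescriptorMatrix(x, spec)
  if (nrow(dm@values) < 2) stop("template map needs a cohort of >= 2 proteins")
  dm <- normalizeDescriptorMatrix(dm)
  fdm <- featureDistanceMatrix(dm)
  emb <- reduceTo2D(fdm, method = method, seed = seed)
  allocateCoordinates(emb, gridSide = gridSide, method = method,
                      seed = seed, spec = dm@spec, featMin = dm@featMin,
                      featMax = dm@featMax)
}

#' Render a protein's multi-channel feature-map image
#'
#' Places the protein's normalized descriptor intensities at their assigned
#' grid cells, one channel per descriptor class (in spec order); all other
#' cells are zero. Raw descriptor vectors are normalized with the map's
#' stored reference min/max and clipped to [0,1].
#'
#' @param descriptor numeric vector of length `spec$total` (raw by default).
#' @param map a [TemplateMap-class].
#' @param normalized set TRUE if `descriptor` is already normalized.
#' @return numeric array, channels x gridSide x gridSide.
#' @export
makeProMap <- function(descriptor, map, normalized = FALSE) {
  spec <- map@spec
  if (length(descriptor) != length(map@assignment))
    stop("descriptor length ", length(descriptor),
         " does not match the template map (", length(map@assignment), ")")
  v <- if (normalized) pmin(pmax(descriptor, 0), 1) else
    as.numeric(.normalizeWith(matrix(descriptor, 1), map@featMin,
                              map@featMax))
  S <- map@gridSide
  nc <- length(spec$classes)
  tensor <- array(0, dim = c(nc, S, S))
  cells <- map@assignment
  rows <- (cells - 1L) %/% S + 1L
  cols <- (cells - 1L) %% S + 1L
  for (k in seq_len(nc)) {
    cl <- spec$classes[[k]]
    idx <- cl$from:cl$to
    tensor[cbind(k, rows[idx], cols[idx])] <- v[idx]
  }
  tensor
}

#' Protein-similarity vector against a reference cohort
#'
#' For a protein in the reference cohort, returns its column of the protein
#' distance matrix (self-entry 0). For an unseen protein, computes the same
#' cosine distances from its normalized descriptor row to every reference
#' row.
#'
#' @param x a protein id (in the reference), a raw descriptor vector, or a
#'   record `list(id=, sequence=)`.
#' @param reference normalized reference [DescriptorMatrix-class].
#' @param pdm optional precomputed [proteinDistanceMatrix()] of the
#'   reference.
#' @return numeric vector of length `nrow(reference)`, entries in [0,2],
#'   named by reference protein ids.
#' @export
makeProSim <- function(x, reference, pdm = NULL) {
  stopifnot(is(reference, "DescriptorMatrix"), isTRUE(reference@normalized))
  if (!nrow(reference@values)) stop("empty reference cohort")
  if (is.character(x) && length(x) == 1 && x %in% reference@proteinIds) {
    if (!is.null(pdm)) return(pdm[, x])
    return(proteinDistanceMatrix(reference)[, x])
  }
  desc <- if (is.list(x) && !is.null(x$sequence))
    assembleDescriptorVector(x$sequence, reference@spec) else
    as.numeric(x)
  q <- as.numeric(.normalizeWith(matrix(desc, 1), reference@featMin,
                                 reference@featMax))
  qn <- sqrt(sum(q^2))
  refNrm <- sqrt(rowSums(reference@values^2))
  sims <- if (qn == 0) rep(0, nrow(reference@values)) else {
    s <- as.numeric(reference@values %*% q) / (refNrm * qn)
    s[refNrm == 0] <- 0
    s
  }
  d <- 1 - sims
  d[refNrm == 0 | qn == 0] <- 1
  d <- pmin(pmax(d, 0), 2)
  # exact duplicates of a reference row are distance 0 despite rounding
  d[d < 1e-12] <- 0
  names(d) <- reference@proteinIds
  d
}

#' Serialize and restore a template map
#'
#' Plain-JSON round trip: every slot (including the full-precision
#' embedding and normalization statistics) is written with maximal digits
#' so `readTemplateMap(writeTemplateMap(m, f))` reproduces `m` exactly.
#'
#' @param map a [TemplateMap-class].
#' @param path JSON file path.
#' @return `path` (write) or a [TemplateMap-class] (read).
#' @export
writeTemplateMap <- function(map, path) {
  specClasses <- lapply(map@spec$classes, function(cl) list(
    name = cl$name, length = cl$length, from = cl$from, to = cl$to,
    params = cl$params))
  # doubles go out as %.17g strings so the round trip is bit-exact
  hex <- function(v) sprintf("%.17g", v)
  payload <- list(
    gridSide = map@gridSide, assignment = map@assignment,
    embedding = hex(as.numeric(map@embedding)), method = map@method,
    seed = map@seed, featMin = hex(map@featMin),
    featMax = hex(map@featMax),
    specTotal = map@spec$total, specMinLength = map@spec$minLength,
    specClasses = specClasses
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTemplateMap
#' @export
readTemplateMap <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(z) vapply(z, as.numeric, 0)
  classes <- lapply(p$specClasses, function(cl) list(
    name = cl$name, length = as.integer(cl$length),
    params = lapply(cl$params, as.numeric),
    from = as.integer(cl$from), to = as.integer(cl$to)))
  spec <- list(classes = classes, total = as.integer(p$specTotal),
               minLength = as.integer(p$specMinLength))
  new("TemplateMap", gridSide = as.integer(p$gridSide),
      assignment = vapply(p$assignment, as.integer, 0L),
      embedding = matrix(num(p$embedding), ncol = 2),
      method = p$method, seed = as.integer(p$seed), spec = spec,
      featMin = num(p$featMin), featMax = num(p$featMax))
}
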