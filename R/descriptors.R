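#' Sequence descriptor classes
#'
#' The seven descriptor classes that make up the default 1,484-dimensional
#' protein feature vector: amino-acid composition (AAC), type-I pseudo
#' amino-acid composition (PAAC), amphiphilic pseudo amino-acid composition
#' (APAAC), Moreau-Broto/Moran/Geary autocorrelations over eight AAindex
#' property scales, quasi-sequence-order descriptors (QSO) over two residue
#' distance matrices, composition/transition/distribution of seven
#' physicochemical groupings (CTD), and conjoint-triad frequencies over the
#' standard seven-cluster alphabet.
#'
#' @param sequence character scalar over the 20 canonical amino-acid
#'   letters (see [sanitizeSequences()]).
#' @param lambda integer, number of sequence-order correlation tiers for
#'   PAAC/APAAC; requires `nchar(sequence) > lambda`.
#' @param w numeric weight of the sequence-order terms.
#' @param maxLag integer, largest lag for autocorrelation/QSO.
#' @param properties numeric matrix of standardized property scales
#'   (rows = scales, columns = the 20 residues); defaults to the eight
#'   packaged AAindex scales.
#' @return A named numeric vector; lengths are 20 (AAC), `20 + lambda`
#'   (PAAC), `20 + 2*lambda` (APAAC), `3 * nrow(properties) * maxLag`
#'   (autocorrelation), 147 (CTD), 343 (conjoint triad) and
#'   `2*maxLag + 2*(20 + maxLag)` (QSO).
#' @examples
#' computeAAC("ACDEFGHIKLMNPQRSTVWY")
#' length(computePAAC(paste(rep("ACDEFG", 10), collapse = ""), lambda = 5))
#' @name descriptors
NULL

.seqInts <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("sequence must be a non-empty character scalar")
  x <- match(strsplit(sequence, "")[[1]], .AA)
  if (anyNA(x))
    stop("sequence contains non-canonical residues; run sanitizeSequences()")
  x
}

#' @rdname descriptors
#' @export
computeAAC <- function(sequence) {
  x <- .seqInts(sequence)
  out <- tabulate(x, nbins = 20) / length(x)
  names(out) <- paste0("AAC.", .AA)
  out
}

# Type-I PAAC correlation between residues i and j: mean squared difference
# of the three standardized property values
.paacTheta <- function(x, k, scales) {
  L <- length(x)
  i <- seq_len(L - k)
  mean(colMeans((scales[, x[i], drop = FALSE] -
                 scales[, x[i + k], drop = FALSE])^2))
}

#' @rdname descriptors
#' @export
computePAAC <- function(sequence, lambda = 30, w = 0.05) {
  x <- .seqInts(sequence)
  if (length(x) <= lambda)
    stop("sequence length (", length(x), ") must exceed lambda (", lambda,
         "); shorten lambda or pad the sequence")
  scales <- .paacScales()
  f <- tabulate(x, nbins = 20) / length(x)
  theta <- if (lambda > 0)
    vapply(seq_len(lambda), function(k) .paacTheta(x, k, scales), 0) else
    numeric(0)
  denom <- sum(f) + w * sum(theta)
  out <- c(f / denom, w * theta / denom)
  names(out) <- c(paste0("PAAC.", .AA),
                  if (lambda > 0) paste0("PAAC.lam", seq_len(lambda)))
  out
}

#' @rdname descriptors
#' @export
computeAPAAC <- function(sequence, lambda = 30, w = 0.05) {
  x <- .seqInts(sequence)
  if (length(x) <= lambda)
    stop("sequence length (", length(x), ") must exceed lambda (", lambda,
         "); shorten lambda or pad the sequence")
  scales <- .paacScales()[c("hydrophobicity", "hydrophilicity"), ,
                          drop = FALSE]
  f <- tabulate(x, nbins = 20) / length(x)
  L <- length(x)
  tau <- numeric(2 * lambda)
  if (lambda > 0) {
    for (k in seq_len(lambda)) {
      i <- seq_len(L - k)
      tau[2 * k - 1] <- mean(scales[1, x[i]] * scales[1, x[i + k]])
      tau[2 * k] <- mean(scales[2, x[i]] * scales[2, x[i + k]])
    }
  }
  denom <- sum(f) + w * sum(tau)
  out <- c(f / denom, w * tau / denom)
  names(out) <- c(paste0("APAAC.", .AA),
                  if (lambda > 0)
                    paste0("APAAC.", rep(c("H1.", "H2."), lambda),
                           rep(seq_len(lambda), each = 2)))
  out
}

#' @rdname descriptors
#' @export
computeAutocorrelation <- function(sequence, properties = .autocorrScales(),
                                   maxLag = 30) {
  x <- .seqInts(sequence)
  L <- length(x)
  if (L <= maxLag)
    stop("sequence length (", L, ") must exceed maxLag (", maxLag, ")")
  nP <- nrow(properties)
  out <- numeric(3 * nP * maxLag)
  nm <- character(3 * nP * maxLag)
  pos <- 0
  for (p in seq_len(nP)) {
    v <- properties[p, x]
    vbar <- mean(v)
    centered <- v - vbar
    ssTot <- sum(centered^2)
    prop <- rownames(properties)[p]
    if (is.null(prop)) prop <- paste0("prop", p)
    for (d in seq_len(maxLag)) {
      i <- seq_len(L - d)
      mb <- sum(v[i] * v[i + d]) / (L - d)
      if (ssTot > 0) {
        moran <- (sum(centered[i] * centered[i + d]) / (L - d)) /
          (ssTot / L)
        geary <- (sum((v[i] - v[i + d])^2) / (2 * (L - d))) /
          (ssTot / (L - 1))
      } else {
        # realized property track is constant: Moran/Geary undefined
        moran <- 0
        geary <- 0
      }
      out[pos + c(1, 2, 3)] <- c(mb, moran, geary)
      nm[pos + c(1, 2, 3)] <- paste0(c("MB.", "Moran.", "Geary."),
                                     prop, ".lag", d)
      pos <- pos + 3
    }
  }
  names(out) <- nm
  out
}

#' @rdname descriptors
#' @export
computeCTD <- function(sequence) {
  x <- .seqInts(sequence)
  L <- length(x)
  if (L < 2) stop("CTD transitions need sequence length >= 2")
  groups <- .ctdGroups()
  out <- numeric(0)
  for (g in names(groups)) {
    cls <- integer(20)
    names(cls) <- .AA
    for (k in 1:3) cls[groups[[g]][[k]]] <- k
    track <- cls[x]
    comp <- tabulate(track, nbins = 3) / L
    # transitions between distinct classes, unordered pairs (1,2),(1,3),(2,3)
    a <- track[-L]; b <- track[-1]
    trans <- c(sum((a == 1 & b == 2) | (a == 2 & b == 1)),
               sum((a == 1 & b == 3) | (a == 3 & b == 1)),
               sum((a == 2 & b == 3) | (a == 3 & b == 2))) / (L - 1)
    distr <- numeric(15)
    for (k in 1:3) {
      posk <- which(track == k)
      if (length(posk)) {
        q <- posk[pmax(1, ceiling(length(posk) * c(0.0001, .25, .5, .75, 1)))]
        distr[(k - 1) * 5 + 1:5] <- q / L
      }
    }
    block <- c(comp, trans, distr)
    names(block) <- paste0("CTD.", g, ".",
                           c(paste0("comp", 1:3), paste0("trans", 1:3),
                             paste0("dist", rep(1:3, each = 5), ".",
                                    rep(c("first", "q25", "q50", "q75",
                                          "q100"), 3))))
    out <- c(out, block)
  }
  out
}

#' @rdname descriptors
#' @export
computeConjointTriad <- function(sequence) {
  x <- .seqInts(sequence)
  L <- length(x)
  if (L < 3) stop("conjoint triad needs sequence length >= 3")
  cl <- .triadClassOf()[.AA[x]]
  idx <- (cl[1:(L - 2)] - 1) * 49 + (cl[2:(L - 1)] - 1) * 7 + cl[3:L]
  out <- tabulate(idx, nbins = 343) / (L - 2)
  names(out) <- paste0("CT.", rep(1:7, each = 49), ".",
                       rep(rep(1:7, each = 7), 7), ".", rep(1:7, 49))
  out
}

#' @rdname descriptors
#' @export
computeQSO <- function(sequence, maxLag = 21, w = 0.1) {
  x <- .seqInts(sequence)
  L <- length(x)
  if (L <= maxLag)
    stop("sequence length (", L, ") must exceed maxLag (", maxLag, ")")
  mats <- list(grantham = .granthamDistance(), physchem = .physchemDistance())
  f <- tabulate(x, nbins = 20) / length(x)
  taus <- qsos <- list()
  for (nmMat in names(mats)) {
    D <- mats[[nmMat]]
    tau <- vapply(seq_len(maxLag), function(d) {
      i <- seq_len(L - d)
      sum(D[cbind(x[i], x[i + d])]^2)
    }, 0)
    qso <- c(f, w * tau) / (sum(f) + w * sum(tau))
    names(tau) <- paste0("QSO.", nmMat, ".tau", seq_len(maxLag))
    names(qso) <- paste0("QSO.", nmMat, ".",
                         c(.AA, paste0("X", 20 + seq_len(maxLag))))
    taus[[nmMat]] <- tau
    qsos[[nmMat]] <- qso
  }
  # coupling numbers for both matrices first, then the QSO descriptors
  c(unlist(unname(taus)), unlist(unname(qsos)))
}

#' Default seven-class descriptor specification
#'
#' Defines the ordered class list and per-class parameters whose lengths sum
#' to 1,484: AAC (20), PAAC with lambda 30 (50), APAAC with lambda 30 (80),
#' autocorrelation over 8 scales and 30 lags (720), QSO with max lag 21
#' (124), CTD (147) and conjoint triad (343). The class order fixes the
#' channel order of feature-map images. The shortest admissible sequence has
#' 31 residues (autocorrelation lag and PAAC lambda both 30).
#'
#' @param classes character, subset of the seven class names (in the order
#'   given); defaults to all seven.
#' @param paacLambda,apaacLambda,autocorrMaxLag,qsoMaxLag,paacW,apaacW,qsoW
#'   per-class parameters.
#' @return A list with elements `classes` (each with name, length, params,
#'   slice start/end) and `total`.
#' @export
defaultDescriptorSpec <- function(classes = c("aac", "paac", "apaac",
                                              "autocorrelation", "qso",
                                              "physicochemical_ctd",
                                              "molecular_interaction_triad"),
                                  paacLambda = 30, apaacLambda = 30,
                                  autocorrMaxLag = 30, qsoMaxLag = 21,
                                  paacW = 0.05, apaacW = 0.05, qsoW = 0.1) {
  known <- c(aac = 20, paac = 20 + paacLambda, apaac = 20 + 2 * apaacLambda,
             autocorrelation = 3 * 8 * autocorrMaxLag,
             qso = 2 * qsoMaxLag + 2 * (20 + qsoMaxLag),
             physicochemical_ctd = 147, molecular_interaction_triad = 343)
  bad <- setdiff(classes, names(known))
  if (length(bad)) stop("unknown descriptor class: ", paste(bad, collapse = ", "))
  params <- list(
    aac = list(),
    paac = list(lambda = paacLambda, w = paacW),
    apaac = list(lambda = apaacLambda, w = apaacW),
    autocorrelation = list(maxLag = autocorrMaxLag),
    qso = list(maxLag = qsoMaxLag, w = qsoW),
    physicochemical_ctd = list(),
    molecular_interaction_triad = list()
  )
  cls <- list()
  pos <- 0L
  for (nm in classes) {
    len <- as.integer(known[nm])
    cls[[nm]] <- list(name = nm, length = len, params = params[[nm]],
                      from = pos + 1L, to = pos + len)
    pos <- pos + len
  }
  minLen <- max(2, if ("paac" %in% classes) paacLambda + 1 else 0,
                if ("apaac" %in% classes) apaacLambda + 1 else 0,
                if ("autocorrelation" %in% classes) autocorrMaxLag + 1 else 0,
                if ("qso" %in% classes) qsoMaxLag + 1 else 0,
                if ("molecular_interaction_triad" %in% classes) 3 else 0)
  list(classes = unname(cls), total = pos, minLength = as.integer(minLen))
}

.computeClass <- function(cl, sequence) {
  switch(cl$name,
    aac = computeAAC(sequence),
    paac = computePAAC(sequence, cl$params$lambda, cl$params$w),
    apaac = computeAPAAC(sequence, cl$params$lambda, cl$params$w),
    autocorrelation = computeAutocorrelation(sequence,
                                             maxLag = cl$params$maxLag),
    qso = computeQSO(sequence, cl$params$maxLag, cl$params$w),
    physicochemical_ctd = computeCTD(sequence),
    molecular_interaction_triad = computeConjointTriad(sequence),
    stop("unknown descriptor class: ", cl$name)
  )
}

#' Assemble the full descriptor vector of a sequence
#'
#' Concatenates the spec's classes in order; the result has length
#' `spec$total` (1,484 under the default spec).
#'
#' @param sequence sanitized amino-acid sequence.
#' @param spec a descriptor specification from [defaultDescriptorSpec()].
#' @return named numeric vector of length `spec$total`.
#' @export
assembleDescriptorVector <- function(sequence, spec = defaultDescriptorSpec()) {
  if (nchar(sequence) < spec$minLength)
    stop("sequence length ", nchar(sequence), " is below the spec minimum ",
         spec$minLength)
  out <- vector("list", length(spec$classes))
  for (k in seq_along(spec$classes)) {
    cl <- spec$classes[[k]]
    v <- tryCatch(.computeClass(cl, sequence), error = function(e)
      stop("descriptor class '", cl$name, "': ", conditionMessage(e),
           call. = FALSE))
    if (length(v) != cl$length)
      stop("descriptor class '", cl$name, "' returned length ", length(v),
           ", expected ", cl$length)
    out[[k]] <- v
  }
  unlist(out)
}

#' Compute the cohort descriptor matrix
#'
#' Applies [assembleDescriptorVector()] to every record and stacks the
#' results into an (unnormalized) [DescriptorMatrix-class].
#'
#' @param records a list of protein records as returned by [readFasta()]
#'   (each with elements `id` and `sequence`).
#' @param spec descriptor specification.
#' @return A [DescriptorMatrix-class] with `normalized = FALSE`.
#' @export
computeDescriptorMatrix <- function(records, spec = defaultDescriptorSpec()) {
  if (!length(records)) stop("empty cohort")
  ids <- vapply(records, `[[`, "", "id")
  vals <- matrix(0, length(records), spec$total,
                 dimnames = list(ids, NULL))
  for (i in seq_along(records)) {
    vals[i, ] <- assembleDescriptorVector(records[[i]]$sequence, spec)
  }
  colnames(vals) <- names(assembleDescriptorVector(
    records[[1]]$sequence, spec))
  new("DescriptorMatrix", values = vals, proteinIds = ids, spec = spec,
      featMin = numeric(0), featMax = numeric(0), normalized = FALSE)
}
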