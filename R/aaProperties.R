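# Residue property tables backing the descriptor classes. All numeric
# scales come from published AAindex entries shipped with seqinr, so no
# hand-typed property values and no network access are involved.

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

.cache <- new.env(parent = emptyenv())

.aaindexScale <- function(accession) {
  key <- paste0("scale_", accession)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  if (is.null(.cache$aaindex)) {
    e <- new.env()
    utils::data("aaindex", package = "seqinr", envir = e)
    .cache$aaindex <- e$aaindex
  }
  entry <- .cache$aaindex[[accession]]
  if (is.null(entry)) stop("AAindex accession not found: ", accession)
  v <- entry$I[.AA3[.AA]]
  names(v) <- .AA
  .cache[[key]] <- v
  v
}

# z-score a 20-value scale over the alphabet (population convention is
# irrelevant downstream; sample sd is used and documented)
.standardizeScale <- function(v) (v - mean(v)) / stats::sd(v)

# Hydrophobicity, hydrophilicity and residue mass: the canonical property
# triple of pseudo amino-acid composition. Molecular weight differs from
# side-chain mass by a constant, which standardization removes.
.paacScaleAccessions <- c(
  hydrophobicity = "CIDH920105",
  hydrophilicity = "HOPT810101",
  mass = "FASG760101"
)

.paacScales <- function() {
  if (is.null(.cache$paac)) {
    m <- t(vapply(.paacScaleAccessions,
                  function(a) .standardizeScale(.aaindexScale(a)),
                  numeric(20)))
    colnames(m) <- .AA
    .cache$paac <- m
  }
  .cache$paac
}

# Eight standard AAindex scales for the autocorrelation class
.autocorrAccessions <- c(
  "CIDH920105", "BHAR880101", "CHAM820101", "CHAM820102",
  "CHOC760101", "BIGC670101", "CHAM810101", "DAYM780201"
)

.autocorrScales <- function() {
  if (is.null(.cache$autocorr)) {
    m <- t(vapply(.autocorrAccessions,
                  function(a) .standardizeScale(.aaindexScale(a)),
                  numeric(20)))
    rownames(m) <- .autocorrAccessions
    colnames(m) <- .AA
    .cache$autocorr <- m
  }
  .cache$autocorr
}

# Seven three-class physicochemical groupings used by the
# composition/transition/distribution class (standard alphabet splits)
.ctdGroups <- function() list(
  hydrophobicity = list(c("R","K","E","D","Q","N"),
                        c("G","A","S","T","P","H","Y"),
                        c("C","L","V","I","M","F","W")),
  vdw_volume = list(c("G","A","S","T","P","D","C"),
                    c("N","V","E","Q","I","L"),
                    c("M","H","K","F","R","Y","W")),
  polarity = list(c("L","I","F","W","C","M","V","Y"),
                  c("P","A","T","G","S"),
                  c("H","Q","R","K","N","E","D")),
  polarizability = list(c("G","A","S","D","T"),
                        c("C","P","N","V","E","Q","I","L"),
                        c("K","M","H","F","R","Y","W")),
  charge = list(c("K","R"),
                c("A","N","C","Q","G","H","I","L","M","F","P","S","T","W","Y","V"),
                c("D","E")),
  secondary_structure = list(c("E","A","L","M","Q","K","R","H"),
                             c("V","I","Y","C","W","F","T"),
                             c("G","N","P","S","D")),
  solvent_accessibility = list(c("A","L","F","C","G","I","V","W"),
                               c("R","K","Q","E","N","D"),
                               c("M","P","S","T","H","Y"))
)

# Seven-cluster alphabet of the conjoint-triad class
.triadClusters <- function() list(
  c("A","G","V"), c("I","L","F","P"), c("Y","M","T","S"),
  c("H","N","Q","W"), c("R","K"), c("D","E"), c("C")
)

.triadClassOf <- function() {
  if (is.null(.cache$triadClass)) {
    cl <- integer(20)
    names(cl) <- .AA
    for (k in seq_along(.triadClusters())) cl[.triadClusters()[[k]]] <- k
    .cache$triadClass <- cl
  }
  .cache$triadClass
}

# Grantham-style residue distance: weighted composition/polarity/volume
# difference (weights 1.833, 0.1018, 0.000399), square-rooted and scaled so
# the mean off-diagonal distance is 100, then normalized to max 1 for use
# as a sequence-order coupling matrix.
.granthamDistance <- function() {
  if (is.null(.cache$grantham)) {
    cpv <- rbind(c = .aaindexScale("GRAR740101"),
                 p = .aaindexScale("GRAR740102"),
                 v = .aaindexScale("GRAR740103"))
    w <- c(1.833, 0.1018, 0.000399)
    d <- matrix(0, 20, 20, dimnames = list(.AA, .AA))
    for (i in 1:20) for (j in 1:20)
      d[i, j] <- sqrt(sum(w * (cpv[, i] - cpv[, j])^2))
    d <- d * 100 / mean(d[upper.tri(d)])
    .cache$grantham <- d / max(d)
  }
  .cache$grantham
}

# Physicochemical residue distance over the standardized PAAC property
# triple (hydrophobicity, hydrophilicity, mass), normalized to max 1
.physchemDistance <- function() {
  if (is.null(.cache$physchem)) {
    s <- .paacScales()
    d <- matrix(0, 20, 20, dimnames = list(.AA, .AA))
    for (i in 1:20) for (j in 1:20)
      d[i, j] <- sqrt(sum((s[, i] - s[, j])^2))
    .cache$physchem <- d / max(d)
  }
  .cache$physchem
}
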