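# The structural dissimilarity metric (SDM) and the all-pairs matrix.
#
# For a pair of domains:
#   PFTE = n_equivalent / length of the smaller domain
#   SRMS = 1 - RMSD / 3.0            (clamped to [0, 1])
#   w1   = ((1 - PFTE) + (1 - SRMS)) / 2,  w2 = (PFTE + SRMS) / 2
#   SDM  = -100 * log10(w1 * PFTE + w2 * SRMS)
# w1 + w2 = 1 by construction. The log argument is clamped below at
# SDM_EPS = 1e-4 so that totally dissimilar pairs score the finite cap
# -100*log10(1e-4) = 400, as distance-based tree methods require finite
# entries.

SDM_EPS <- 1e-4
SDM_CAP <- 400

#' Proportion of topologically equivalent residues (PFTE)
#'
#' @param nEquivalent number of equivalenced residue pairs.
#' @param lenA,lenB lengths (resolved Cα counts) of the two domains.
#' @return `nEquivalent / min(lenA, lenB)`, a fraction in `[0, 1]`.
#' @examples
#' computePFTE(100, 160, 180)  # 0.625
#' @export
computePFTE <- function(nEquivalent, lenA, lenB) {
  if (any(lenA < 3L) || any(lenB < 3L)) stop("domain lengths must be >= 3")
  m <- pmin(lenA, lenB)
  if (any(nEquivalent > m))
    stop("nEquivalent exceeds the length of the smaller domain")
  if (any(nEquivalent < 0)) stop("nEquivalent must be non-negative")
  nEquivalent / m
}

#' Scaled RMSD term (SRMS)
#'
#' Maps superposition quality onto `[0, 1]`: 1 at RMSD 0, 0 at the 3
#' Angstrom equivalence cutoff and beyond (RMSD above the cutoff can arise
#' from imported alignments and is clamped).
#'
#' @param rmsd RMSD in Angstrom over the equivalenced residues.
#' @return `max(0, min(1, 1 - rmsd/3))`.
#' @export
computeSRMS <- function(rmsd) {
  if (any(!is.na(rmsd) & rmsd < 0)) stop("rmsd must be non-negative")
  pmax(0, pmin(1, 1 - rmsd / 3.0))
}

#' Structural dissimilarity metric (SDM)
#'
#' Self-weighted combination of PFTE and SRMS on a -100*log10 scale:
#' 0 for identical structures, up to the cap of 400 for pairs with no
#' detectable structural correspondence.
#'
#' @param pfte,srms fractions in `[0, 1]` (vectorized).
#' @return data.frame with columns `w1`, `w2` and `sdm`.
#' @examples
#' computeSDM(0.5, 0.5)$sdm  # -100*log10(0.5) = 30.103
#' @export
computeSDM <- function(pfte, srms) {
  if (any(pfte < 0 | pfte > 1) || any(srms < 0 | srms > 1))
    stop("pfte and srms must lie in [0, 1]")
  w1 <- ((1 - pfte) + (1 - srms)) / 2
  w2 <- (pfte + srms) / 2
  g <- pmax(w1 * pfte + w2 * srms, SDM_EPS)
  data.frame(w1 = w1, w2 = w2, sdm = -100 * log10(g))
}

#' Per-pair SDM table for a set of alignments
#'
#' Applies the PFTE/SRMS/SDM chain to each structural alignment. An
#' alignment with no equivalenced residues is maximally dissimilar
#' (PFTE = 0, SRMS = 0, SDM = 400).
#'
#' @param alignments list of [StructuralAlignment-class], one per unordered
#'   pair.
#' @param structures named list of [DomainStructure-class] supplying domain
#'   lengths.
#' @return data.frame with columns `id_a`, `id_b`, `n_equiv`, `rmsd`,
#'   `pfte`, `srms`, `w1`, `w2`, `sdm`.
#' @export
sdmPairTable <- function(alignments, structures) {
  lens <- vapply(structures, domainLength, integer(1))
  names(lens) <- vapply(structures, domainId, character(1))
  rows <- lapply(alignments, function(al) {
    if (!al@idA %in% names(lens) || !al@idB %in% names(lens))
      stop("alignment ", al@idA, " vs ", al@idB,
           " references a domain missing from 'structures'")
    n <- al@nEquivalent
    pfte <- computePFTE(n, lens[[al@idA]], lens[[al@idB]])
    srms <- if (n == 0L) 0 else computeSRMS(al@rmsd)
    s <- computeSDM(pfte, srms)
    data.frame(id_a = al@idA, id_b = al@idB, n_equiv = n,
               rmsd = ifelse(n == 0L, NA_real_, al@rmsd),
               pfte = pfte, srms = srms, w1 = s$w1, w2 = s$w2, sdm = s$sdm)
  })
  do.call(rbind, rows)
}

#' Assemble the all-pairs SDM dissimilarity matrix
#'
#' @param pairTable per-pair table from [sdmPairTable] (or any data.frame
#'   with `id_a`, `id_b` and a value column).
#' @param labels domain label order for the matrix; defaults to the order
#'   of first appearance in the table.
#' @param value name of the value column (default `"sdm"`).
#' @return a [DissimilarityMatrix-class]; errors listing any absent pairs.
#' @export
buildDissimilarityMatrix <- function(pairTable, labels = NULL,
                                     value = "sdm") {
  if (is.null(labels)) labels <- unique(c(pairTable$id_a, pairTable$id_b))
  n <- length(labels)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(m) <- 0
  for (k in seq_len(nrow(pairTable))) {
    i <- match(pairTable$id_a[k], labels)
    j <- match(pairTable$id_b[k], labels)
    if (is.na(i) || is.na(j))
      stop("pair table references unknown label: ",
           pairTable$id_a[k], " / ", pairTable$id_b[k])
    m[i, j] <- m[j, i] <- pairTable[[value]][k]
  }
  if (anyNA(m)) {
    miss <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    stop("incomplete pair set; missing: ",
         paste(labels[miss[, 1]], labels[miss[, 2]], sep = "-",
               collapse = ", "))
  }
  DissimilarityMatrix(m, labels)
}

#' Read and write square PHYLIP distance matrices
#'
#' Full square format: taxon count on the first line, then one row per
#' taxon with the label padded to 10 characters. Labels longer than 10
#' characters are truncated with a warning (uniqueness is enforced).
#'
#' @param dm a [DissimilarityMatrix-class].
#' @param path file path.
#' @return `writePhylip` returns `path` invisibly; `readPhylip` returns a
#'   [DissimilarityMatrix-class].
#' @export
writePhylip <- function(dm, path) {
  labs <- labels(dm)
  if (any(nchar(labs) > 10L)) {
    warning("labels longer than 10 characters truncated for PHYLIP output")
    labs <- substr(labs, 1L, 10L)
    if (anyDuplicated(labs))
      stop("label truncation to 10 characters creates duplicates")
  }
  v <- as.matrix(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(labs)), con)
  for (i in seq_along(labs)) {
    writeLines(paste0(formatC(labs[i], width = -10),
                      paste(sprintf("%10.6f", v[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' @rdname writePhylip
#' @export
readPhylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  labs <- character(n)
  v <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    labs[i] <- trimws(substr(lines[i + 1], 1L, 10L))
    v[i, ] <- as.numeric(strsplit(trimws(substring(lines[i + 1], 11L)),
                                  "[[:space:]]+")[[1]])
  }
  # guard against asymmetry introduced by fixed-precision output
  v <- (v + t(v)) / 2
  diag(v) <- 0
  DissimilarityMatrix(v, labs)
}
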