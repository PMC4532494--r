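#' @import methods
#' @importFrom stats rnorm rpois runif setNames cor
#' @importFrom utils read.delim write.table head combn
NULL

setOldClass("phylo")

#' Cα trace of one protein domain
#'
#' Ordered Cα coordinates plus one-letter sequence for a single protein
#' domain (one chain segment). Residue identity for all alignment math is
#' the positional index after Cα filtering; author residue numbers are
#' retained for reporting only.
#'
#' @slot id single label string.
#' @slot coords numeric n x 3 matrix of Cα coordinates (Angstrom).
#' @slot aa character vector of one-letter amino-acid codes ('X' unknown).
#' @slot resno integer vector of author residue numbers.
#'
#' @examples
#' d <- makeTemplate(40, seed = 1)
#' domainLength(d)
#' substr(domainSequence(d), 1, 10)
#' @exportClass DomainStructure
setClass("DomainStructure",
  representation(id = "character", coords = "matrix", aa = "character",
                 resno = "integer"))

setValidity("DomainStructure", function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be n x 3")
  if (!is.numeric(object@coords) || anyNA(object@coords))
    msg <- c(msg, "coords must be numeric and complete")
  if (length(object@aa) != n) msg <- c(msg, "aa length must match coords")
  if (length(object@resno) != n) msg <- c(msg, "resno length must match coords")
  if (length(msg)) msg else TRUE
})

#' Residue-level structural alignment of two domains
#'
#' Result of superposing domain `b` onto domain `a`: the equivalenced
#' residue pairs (sequential, non-crossing, 1-based positional indices),
#' the optimal rigid transform (`x_b %*% t(rotation) + translation`
#' maps b into a's frame), and the RMSD over the equivalenced pairs.
#'
#' @slot idA,idB domain labels.
#' @slot pairs integer m x 2 matrix of equivalenced positions (1-based),
#'   strictly increasing in both columns.
#' @slot rotation 3 x 3 proper rotation matrix (det +1).
#' @slot translation length-3 numeric vector (Angstrom).
#' @slot rmsd RMSD over `pairs` (Angstrom); `NA` when no residues could be
#'   equivalenced.
#' @slot nEquivalent number of equivalenced pairs.
#' @slot converged logical; `TRUE` when the equivalence set stabilised.
#' @slot nIterations iterations used by the refinement.
#' @exportClass StructuralAlignment
setClass("StructuralAlignment",
  representation(idA = "character", idB = "character", pairs = "matrix",
                 rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nEquivalent = "integer",
                 converged = "logical", nIterations = "integer"))

setValidity("StructuralAlignment", function(object) {
  msg <- character()
  p <- object@pairs
  if (ncol(p) != 2L) msg <- c(msg, "pairs must have two columns")
  if (nrow(p) > 1L) {
    if (any(diff(p[, 1]) <= 0) || any(diff(p[, 2]) <= 0))
      msg <- c(msg, "pairs must be strictly increasing in both indices")
  }
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) {
    msg <- c(msg, "rotation must be 3 x 3")
  } else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation must be proper (det +1)")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  if (!is.na(object@rmsd) && object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (object@nEquivalent != nrow(p))
    msg <- c(msg, "nEquivalent must equal nrow(pairs)")
  if (length(msg)) msg else TRUE
})

#' Symmetric labelled dissimilarity matrix
#'
#' Container for an all-pairs dissimilarity matrix (SDM or percent-identity
#' distance): symmetric, zero diagonal, non-negative entries.
#'
#' @slot labels ordered domain labels.
#' @slot values numeric n x n matrix.
#' @exportClass DissimilarityMatrix
setClass("DissimilarityMatrix",
  representation(labels = "character", values = "matrix"))

setValidity("DissimilarityMatrix", function(object) {
  msg <- character()
  v <- object@values
  n <- length(object@labels)
  if (!all(dim(v) == c(n, n))) msg <- c(msg, "values must be n x n")
  else {
    if (anyNA(v)) msg <- c(msg, "values must be complete")
    else {
      if (max(abs(v - t(v))) > 1e-9) msg <- c(msg, "matrix must be symmetric")
      if (any(abs(diag(v)) > 0)) msg <- c(msg, "diagonal must be zero")
      if (any(v < 0)) msg <- c(msg, "entries must be non-negative")
    }
  }
  if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Specification for a synthetic domain family
#'
#' Parameters for diverging a template Cα trace along a known guide tree:
#' Brownian coordinate noise (per-coordinate s.d. `noiseSigma * sqrt(l)`
#' on a branch of length `l`), Poisson single-residue deletions and
#' Poisson residue substitutions, all fully reproducible from `seed`.
#'
#' @slot guideTree rooted `phylo` guide tree with branch lengths in
#'   divergence units.
#' @slot templateLength template length in residues (>= 20).
#' @slot noiseSigma coordinate noise, Angstrom per sqrt(divergence unit).
#' @slot indelRate expected deletions per unit branch length.
#' @slot substitutionRate expected substitutions per unit branch length.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticTreeSpec
setClass("SyntheticTreeSpec",
  representation(guideTree = "phylo", templateLength = "integer",
                 noiseSigma = "numeric", indelRate = "numeric",
                 substitutionRate = "numeric", seed = "integer"))

setValidity("SyntheticTreeSpec", function(object) {
  msg <- character()
  if (object@templateLength < 20L) msg <- c(msg, "templateLength must be >= 20")
  if (object@noiseSigma < 0 || object@indelRate < 0 ||
      object@substitutionRate < 0)
    msg <- c(msg, "rates must be non-negative")
  if (is.null(object@guideTree$edge.length))
    msg <- c(msg, "guide tree must have branch lengths")
  if (length(msg)) msg else TRUE
})
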