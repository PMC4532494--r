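# Accessors and show() methods for the core classes.

#' @rdname DomainStructure-class
#' @export
setMethod("domainId", "DomainStructure", function(object) object@id)

#' @rdname DomainStructure-class
#' @export
setMethod("caCoords", "DomainStructure", function(object) {
  m <- object@coords
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
})

#' @rdname DomainStructure-class
#' @export
setMethod("residueNumbers", "DomainStructure", function(object) object@resno)

#' @rdname DomainStructure-class
#' @export
setMethod("domainLength", "DomainStructure",
          function(object) nrow(object@coords))

#' Extract the one-letter sequence of a domain
#'
#' Returns the amino-acid sequence of the Cα-filtered residues, in chain
#' order; residues of unknown parent type appear as 'X'.
#'
#' @rdname DomainStructure-class
#' @export
setMethod("domainSequence", "DomainStructure",
          function(object) paste(object@aa, collapse = ""))

setMethod("show", "DomainStructure", function(object) {
  cat("DomainStructure '", object@id, "': ", domainLength(object),
      " Ca residues\n", sep = "")
  if (domainLength(object) > 0)
    cat("  sequence: ", substr(domainSequence(object), 1, 40),
        if (domainLength(object) > 40) "..." else "", "\n", sep = "")
})

#' @rdname StructuralAlignment-class
#' @param object a \code{StructuralAlignment}.
#' @export
setMethod("alignedPairs", "StructuralAlignment", function(object) {
  p <- object@pairs
  dimnames(p) <- list(NULL, c("index_a", "index_b"))
  p
})

#' @rdname StructuralAlignment-class
#' @export
setMethod("alignmentRmsd", "StructuralAlignment", function(object) object@rmsd)

#' @rdname StructuralAlignment-class
#' @export
setMethod("nEquivalent", "StructuralAlignment",
          function(object) object@nEquivalent)

#' @rdname StructuralAlignment-class
#' @export
setMethod("alignmentTransform", "StructuralAlignment", function(object)
  list(rotation = object@rotation, translation = object@translation))

#' @rdname StructuralAlignment-class
#' @export
setMethod("isConverged", "StructuralAlignment",
          function(object) object@converged)

setMethod("show", "StructuralAlignment", function(object) {
  cat("StructuralAlignment ", object@idA, " vs ", object@idB, ": ",
      object@nEquivalent, " equivalent residues, rmsd ",
      ifelse(is.na(object@rmsd), "NA", sprintf("%.3f", object@rmsd)),
      " A, ", if (object@converged) "converged" else "not converged",
      " (", object@nIterations, " iterations)\n", sep = "")
})

#' Construct a DissimilarityMatrix
#'
#' @param values symmetric numeric matrix with zero diagonal and
#'   non-negative entries.
#' @param labels optional labels; defaults to `rownames(values)`.
#' @return a \code{DissimilarityMatrix}.
#' @examples
#' m <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' DissimilarityMatrix(m)
#' @export
DissimilarityMatrix <- function(values, labels = rownames(values)) {
  if (is.null(labels))
    stop("labels are required (or provide rownames on 'values')")
  values <- as.matrix(values)
  labels <- unname(as.character(labels))
  dimnames(values) <- list(labels, labels)
  new("DissimilarityMatrix", labels = labels, values = values)
}

#' @rdname DissimilarityMatrix-class
#' @param x a \code{DissimilarityMatrix}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "DissimilarityMatrix", function(x, ...) x@values)

#' @rdname DissimilarityMatrix-class
#' @export
setMethod("labels", "DissimilarityMatrix", function(object, ...) object@labels)

#' @rdname DissimilarityMatrix-class
#' @export
setMethod("dim", "DissimilarityMatrix", function(x) dim(x@values))

setMethod("show", "DissimilarityMatrix", function(object) {
  n <- length(object@labels)
  cat("DissimilarityMatrix: ", n, " x ", n, " (", n * (n - 1) / 2,
      " pairs)\n", sep = "")
  k <- min(n, 5L)
  print(round(object@values[seq_len(k), seq_len(k), drop = FALSE], 3))
  if (n > k) cat("...\n")
})

setMethod("show", "SyntheticTreeSpec", function(object) {
  cat("SyntheticTreeSpec: ", length(object@guideTree$tip.label),
      " leaves, template ", object@templateLength, " residues\n",
      "  noiseSigma = ", object@noiseSigma, " A/sqrt(unit), indelRate = ",
      object@indelRate, ", substitutionRate = ", object@substitutionRate,
      ", seed = ", object@seed, "\n", sep = "")
})
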