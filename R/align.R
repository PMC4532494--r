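# Iterative superposition alignment: seed by exhaustive gapless fragment
# superposition, then alternate (sequence-order-preserving DP over the
# proximity score, Kabsch refit on the equivalenced set) until the
# equivalence set stabilises.

#' Align two domains by iterative superposition
#'
#' Produces the residue-level topological equivalences for a structure
#' pair. Two residues are topologically equivalent when their Cα atoms lie
#' within `cutoff` (default 3 Angstrom) after optimal rigid superposition.
#' The algorithm: (1) seed — superpose every gapless fragment pair
#' (`fragLength` residues on a `stride` grid of start positions) and keep
#' the transform placing the most residues of `b` within `cutoff` of `a`;
#' (2) iterate — score matrix `S(i,j) = max(0, cutoff - d(i,j))`, global
#' order-preserving dynamic programming with linear gap penalty
#' `gapPenalty` per gap position, new equivalence set = aligned pairs with
#' `d <= cutoff`, transform refit by Kabsch on that set; (3) stop when the
#' set is unchanged (`converged`) or after `maxIter` iterations (the
#' iteration with the most equivalences, ties broken by lower RMSD, is
#' returned). If no seed places at least `fragLength` residues within the
#' cutoff the pair is maximally dissimilar: `nEquivalent = 0`,
#' `converged = TRUE`, `rmsd = NA`.
#'
#' @param a,b [DomainStructure-class] objects.
#' @param cutoff topological-equivalence cutoff in Angstrom.
#' @param maxIter maximum refinement iterations.
#' @param fragLength seed fragment length (residues).
#' @param stride seed grid stride (residues).
#' @param gapPenalty linear DP gap penalty per gap position.
#' @return a [StructuralAlignment-class].
#' @examples
#' a <- makeTemplate(80, seed = 1)
#' aln <- iterativeAlign(a, a)
#' stopifnot(nEquivalent(aln) == 80, alignmentRmsd(aln) < 1e-8)
#' @export
iterativeAlign <- function(a, b, cutoff = 3.0, maxIter = 50L,
                           fragLength = 8L, stride = 4L, gapPenalty = 0.5) {
  stopifnot(is(a, "DomainStructure"), is(b, "DomainStructure"))
  if (domainLength(a) < fragLength || domainLength(b) < fragLength)
    stop("degenerate input: structures must have at least ", fragLength,
         " residues")
  res <- .cpp_iterative_align(a@coords, b@coords, cutoff,
                              as.integer(fragLength), as.integer(stride),
                              gapPenalty, as.integer(maxIter))
  pairs <- matrix(as.integer(res$pairs), ncol = 2L)
  # RMSD at numerical-noise level (identical or rigidly copied structures)
  # is snapped to an exact zero so that downstream SDM self-pairs are 0
  rmsd <- res$rmsd
  if (!is.na(rmsd) && rmsd < 1e-9) rmsd <- 0
  aln <- new("StructuralAlignment", idA = domainId(a), idB = domainId(b),
             pairs = pairs, rotation = res$rotation,
             translation = as.numeric(res$translation),
             rmsd = rmsd, nEquivalent = nrow(pairs),
             converged = res$converged,
             nIterations = as.integer(res$n_iterations))
  # hard assertion: every reported equivalence satisfies the cutoff under
  # the reported transform
  if (nrow(pairs) > 0L) {
    bt <- applyTransform(b@coords, res$rotation, as.numeric(res$translation))
    d <- sqrt(rowSums((a@coords[pairs[, 1], , drop = FALSE] -
                       bt[pairs[, 2], , drop = FALSE])^2))
    stopifnot(all(d <= cutoff + 1e-9))
  }
  aln
}

#' Import an externally computed residue-equivalence table
#'
#' Reads a tab-separated equivalence file (header `index_a`, `index_b`,
#' 0-based positional indices as in [writeAlignmentTable]) and recomputes
#' the rigid transform and RMSD by Kabsch superposition over the imported
#' pairs. Intended for alignments computed by external tools (e.g.
#' distance-matrix aligners) in place of [iterativeAlign].
#'
#' @param path equivalence TSV.
#' @param a,b the [DomainStructure-class] objects the indices refer to.
#' @return a [StructuralAlignment-class] (`converged = TRUE`,
#'   `nIterations = 0`).
#' @export
importAlignment <- function(path, a, b) {
  tab <- tryCatch(read.delim(path, header = TRUE),
                  error = function(e) stop("cannot read equivalence file '",
                                           path, "': ", conditionMessage(e)))
  if (!all(c("index_a", "index_b") %in% names(tab)))
    stop("equivalence file must have columns 'index_a' and 'index_b'")
  if (nrow(tab) == 0L) stop("equivalence file is empty: ", path)
  ia <- as.integer(tab$index_a) + 1L   # file is 0-based
  ib <- as.integer(tab$index_b) + 1L
  bad <- which(ia < 1L | ia > domainLength(a) | ib < 1L |
                 ib > domainLength(b))
  if (length(bad))
    stop("out-of-range index at line ", bad[1] + 1L, " of ", path)
  if (nrow(tab) > 1L) {
    cross <- which(diff(ia) <= 0L | diff(ib) <= 0L)
    if (length(cross))
      stop("crossing or non-increasing pair at line ", cross[1] + 2L,
           " of ", path)
  }
  fit <- kabschSuperpose(a@coords[ia, , drop = FALSE],
                         b@coords[ib, , drop = FALSE])
  new("StructuralAlignment", idA = domainId(a), idB = domainId(b),
      pairs = cbind(ia, ib, deparse.level = 0), rotation = fit$rotation,
      translation = fit$translation, rmsd = fit$rmsd,
      nEquivalent = length(ia), converged = TRUE, nIterations = 0L)
}

#' Write an equivalence table for a structural alignment
#'
#' Tab-separated, header `index_a`/`index_b`, 0-based positional indices;
#' the format read back by [importAlignment].
#'
#' @param alignment a [StructuralAlignment-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeAlignmentTable <- function(alignment, path) {
  tab <- data.frame(index_a = alignment@pairs[, 1] - 1L,
                    index_b = alignment@pairs[, 2] - 1L)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
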