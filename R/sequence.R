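# Sequence-side analyses: percent identity from structural equivalences,
# pairwise global (Needleman-Wunsch) alignment, identity histograms and the
# percent-identity distance matrix feeding the sequence NJ tree.

#' Percent identity over a structural alignment
#'
#' Counts matching amino acids across the topologically equivalenced
#' residue pairs; the denominator is the number of equivalenced (non-gap)
#' positions. An empty alignment is reported as 0% with `undefined = TRUE`.
#'
#' @param alignment a [StructuralAlignment-class].
#' @param a,b the aligned [DomainStructure-class] objects.
#' @return one-row data.frame: `id_a`, `id_b`, `n_identical`, `n_aligned`,
#'   `percent_identity`, `undefined`, `source`.
#' @export
identityFromStructuralAlignment <- function(alignment, a, b) {
  p <- alignment@pairs
  nal <- nrow(p)
  nid <- if (nal) sum(a@aa[p[, 1]] == b@aa[p[, 2]]) else 0L
  data.frame(id_a = alignment@idA, id_b = alignment@idB,
             n_identical = as.integer(nid), n_aligned = as.integer(nal),
             percent_identity = if (nal) 100 * nid / nal else 0,
             undefined = nal == 0L, source = "structural")
}

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

#' Global pairwise sequence alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under linear scoring (`match` +1, `mismatch`
#' -1, `gap` -2 by default). Traceback ties prefer match, then a gap in
#' `seqA`, then a gap in `seqB`. Identity is counted over aligned non-gap
#' positions.
#'
#' @param seqA,seqB non-empty sequence strings.
#' @param match,mismatch,gap linear scoring parameters.
#' @param idA,idB labels for the identity record.
#' @return list with `alignedA`/`alignedB` (gapped strings), `score` and
#'   `identity` (one-row data.frame as in
#'   [identityFromStructuralAlignment], `source = "global-sequence"`).
#' @examples
#' globalAlign("AAAA", "AATA")$identity$percent_identity  # 75
#' @export
globalAlign <- function(seqA, seqB, match = 1, mismatch = -1, gap = -2,
                        idA = "a", idB = "b") {
  if (!nchar(seqA) || !nchar(seqB)) stop("sequences must be non-empty")
  ca <- strsplit(seqA, "")[[1]]
  cb <- strsplit(seqB, "")[[1]]
  res <- .cpp_nw_align(base::match(ca, .AA, nomatch = 0L),
                       base::match(cb, .AA, nomatch = 0L),
                       match, mismatch, gap)
  ga <- ifelse(res$ia == 0L, "-", ca[pmax(res$ia, 1L)])
  gb <- ifelse(res$ib == 0L, "-", cb[pmax(res$ib, 1L)])
  nongap <- res$ia > 0L & res$ib > 0L
  nal <- sum(nongap)
  nid <- sum(ca[res$ia[nongap]] == cb[res$ib[nongap]])
  list(alignedA = paste(ga, collapse = ""),
       alignedB = paste(gb, collapse = ""),
       score = res$score,
       identity = data.frame(id_a = idA, id_b = idB,
                             n_identical = as.integer(nid),
                             n_aligned = as.integer(nal),
                             percent_identity = if (nal) 100 * nid / nal
                                                else 0,
                             undefined = nal == 0L,
                             source = "global-sequence"))
}

#' Histogram of pairwise sequence identities
#'
#' Half-open 10-point bins `[0,10), [10,20), ..., [90,100]` over
#' percent-identity records, with per-bin fractions and the cumulative
#' fraction below each bin's upper edge.
#'
#' @param records data.frame with a `percent_identity` column (e.g. rows
#'   from [identityFromStructuralAlignment]), or a numeric vector of
#'   percent identities.
#' @param binWidth bin width in percentage points (default 10).
#' @return data.frame: `bin_low`, `bin_high`, `count`, `fraction`,
#'   `cum_fraction` (fraction with identity `< bin_high`).
#' @export
identityHistogram <- function(records, binWidth = 10) {
  pid <- if (is.data.frame(records)) records$percent_identity else records
  if (!length(pid)) stop("no identity records")
  lo <- seq(0, 100 - binWidth, by = binWidth)
  hi <- lo + binWidth
  counts <- vapply(seq_along(lo), function(i) {
    if (i == length(lo)) sum(pid >= lo[i] & pid <= hi[i])
    else sum(pid >= lo[i] & pid < hi[i])
  }, numeric(1))
  frac <- counts / length(pid)
  data.frame(bin_low = lo, bin_high = hi, count = as.integer(counts),
             fraction = frac, cum_fraction = cumsum(frac))
}

#' Fraction of pairs below an identity threshold
#'
#' @param records as in [identityHistogram].
#' @param threshold percent-identity threshold.
#' @return fraction of records with `percent_identity < threshold`.
#' @export
fractionBelowIdentity <- function(records, threshold) {
  pid <- if (is.data.frame(records)) records$percent_identity else records
  mean(pid < threshold)
}

#' Percent-identity distance matrix
#'
#' `d = 100 - percent_identity` per pair; no substitution-model correction
#' is applied.
#'
#' @param records data.frame of identity records covering every unordered
#'   pair (columns `id_a`, `id_b`, `percent_identity`).
#' @param labels optional label order.
#' @return a [DissimilarityMatrix-class].
#' @export
identityDistanceMatrix <- function(records, labels = NULL) {
  records$dist <- 100 - records$percent_identity
  buildDissimilarityMatrix(records, labels = labels, value = "dist")
}
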