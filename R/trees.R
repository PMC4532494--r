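# Distance-based tree inference: UPGMA, clock-constrained Fitch-Margoliash
# least squares (the classic "Kitsch" approach: minimize
# sum_{i<j} w_ij (d_ij - t_ij)^2 with w = 1/d^power over ultrametric trees),
# neighbor-joining, Newick serialization, cluster extraction and
# Robinson-Foulds comparison. Trees are ape 'phylo' objects throughout.

# ---- internal rooted-tree representation -------------------------------
# leaves 1..n, internal nodes arbitrary ids > n, explicit root; children
# stored per node. Used for NNI search and height optimization.

rtFromPhylo <- function(phy) {
  n <- length(phy$tip.label)
  m <- max(phy$edge)
  parent <- rep(NA_integer_, m)
  children <- vector("list", m)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    parent[ch] <- p
    children[[p]] <- c(children[[p]], ch)
  }
  root <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])
  list(nleaf = n, labels = phy$tip.label, parent = parent,
       children = children, root = root)
}

rtPostorder <- function(rt) {
  out <- integer(0)
  stack <- rt$root
  seen <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    kids <- rt$children[[v]]
    if (length(kids)) stack <- c(stack, kids)
  }
  rev(seen)  # reverse preorder = a valid postorder
}

# convert a rooted representation + node heights to an ape phylo
rtToPhylo <- function(rt, heights) {
  n <- rt$nleaf
  newid <- rep(NA_integer_, length(rt$parent))
  newid[seq_len(n)] <- seq_len(n)
  nxt <- n + 1L
  stack <- rt$root
  pre <- integer(0)
  while (length(stack)) {                       # preorder internal numbering
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    pre <- c(pre, v)
    if (v > n || length(rt$children[[v]])) {
      newid[v] <- nxt; nxt <- nxt + 1L
      stack <- c(stack, rev(rt$children[[v]]))
    }
  }
  edges <- matrix(0L, 0, 2); len <- numeric(0)
  for (v in pre) {
    for (ch in rt$children[[v]]) {
      edges <- rbind(edges, c(newid[v], newid[ch]))
      len <- c(len, heights[v] - (if (ch <= n) 0 else heights[ch]))
    }
  }
  phy <- list(edge = edges, edge.length = len, tip.label = rt$labels,
              Nnode = nxt - n - 1L)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

# leaf sets below every node (list indexed by node id)
rtLeafSets <- function(rt, post) {
  ls <- vector("list", length(rt$parent))
  for (v in post) {
    if (v <= rt$nleaf && !length(rt$children[[v]])) ls[[v]] <- v
    else ls[[v]] <- sort(unlist(ls[rt$children[[v]]]))
  }
  ls
}

# ---- weighted isotonic regression on the tree order --------------------
# minimize sum_v w_v (h_v - y_v)^2 subject to h_child <= h_parent, by
# bottom-up block merging: each node starts as its own block; while any
# still-open block in the subtree has a larger mean than the current
# node's block, merge it in. Exact for tree partial orders.
rtIsotonicHeights <- function(rt, post, y, w) {
  m <- length(rt$parent)
  bmean <- bw <- rep(NA_real_, m)
  mergedInto <- rep(NA_integer_, m)
  open <- vector("list", m)
  internals <- post[post > rt$nleaf | vapply(rt$children[post], length,
                                             1L) > 0]
  for (v in internals) {
    bmean[v] <- y[v]; bw[v] <- w[v]
    os <- unlist(open[rt$children[[v]]])
    repeat {
      if (!length(os)) break
      mx <- which.max(bmean[os])
      if (bmean[os[mx]] <= bmean[v]) break
      b <- os[mx]
      bmean[v] <- (bmean[v] * bw[v] + bmean[b] * bw[b]) / (bw[v] + bw[b])
      bw[v] <- bw[v] + bw[b]
      mergedInto[b] <- v
      os <- os[-mx]
    }
    open[[v]] <- c(os, v)
  }
  h <- rep(0, m)
  for (v in internals) {
    b <- v
    while (!is.na(mergedInto[b])) b <- mergedInto[b]
    h[v] <- bmean[b]
  }
  h
}

# weighted least-squares clock fit for a fixed topology:
# per-node targets y_v = sum(w d)/(2 sum(w)) over pairs whose LCA is v,
# then isotonic projection onto h_child <= h_parent.
rtClockFit <- function(rt, D, W, WD, WD2) {
  post <- rtPostorder(rt)
  ls <- rtLeafSets(rt, post)
  m <- length(rt$parent)
  y <- w <- sw <- swd <- swd2 <- rep(0, m)
  for (v in post) {
    kids <- rt$children[[v]]
    if (length(kids) != 2L) next
    l1 <- ls[[kids[1]]]; l2 <- ls[[kids[2]]]
    sw[v] <- sum(W[l1, l2]); swd[v] <- sum(WD[l1, l2])
    swd2[v] <- sum(WD2[l1, l2])
    y[v] <- swd[v] / (2 * sw[v]); w[v] <- sw[v]
  }
  h <- rtIsotonicHeights(rt, post, y, w)
  ints <- which(sw > 0)
  score <- sum(swd2[ints] - 4 * h[ints] * swd[ints] + 4 * h[ints]^2 * sw[ints])
  list(heights = h, score = score)
}

# all NNI neighbors of a rooted binary tree
rtNniNeighbors <- function(rt) {
  out <- list()
  ids <- seq_along(rt$parent)
  for (v in ids) {
    if (v <= rt$nleaf || is.na(rt$parent[v])) next   # leaf or root
    u <- rt$parent[v]
    s <- setdiff(rt$children[[u]], v)
    for (ci in 1:2) {
      c0 <- rt$children[[v]][ci]
      nb <- rt
      nb$children[[u]] <- c(setdiff(nb$children[[u]], s), c0)
      nb$children[[v]] <- c(setdiff(nb$children[[v]], c0), s)
      nb$parent[s] <- v
      nb$parent[c0] <- u
      out[[length(out) + 1L]] <- nb
    }
  }
  out
}

.checkDM <- function(dm, minN = 2L) {
  stopifnot(is(dm, "DissimilarityMatrix"))
  if (length(labels(dm)) < minN)
    stop("at least ", minN, " taxa are required")
  invisible(dm)
}

# ---- UPGMA -------------------------------------------------------------

#' UPGMA (average-linkage) clock tree
#'
#' Standard unweighted pair-group agglomeration: node heights are half the
#' average dissimilarity at each merge, so the result is rooted and
#' ultrametric. Ties are broken by the lowest label-index pair (clusters
#' ordered by their smallest member's position in `labels(dm)`).
#'
#' @param dm a [DissimilarityMatrix-class] with at least 2 taxa.
#' @return a rooted ultrametric `phylo`.
#' @export
upgmaTree <- function(dm) {
  .checkDM(dm, 2L)
  labs <- labels(dm)
  n <- length(labs)
  D <- as.matrix(dm)
  nodes <- seq_len(n)            # active node ids, ordered by smallest leaf
  sizes <- rep(1L, n)
  m <- 2L * n - 1L
  parent <- rep(NA_integer_, m)
  children <- vector("list", m)
  heights <- rep(0, m)
  nxt <- n + 1L
  while (length(nodes) > 1L) {
    k <- length(nodes)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (D[i, j] < bestd) { bestd <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    ni <- nodes[i]; nj <- nodes[j]
    parent[c(ni, nj)] <- nxt
    children[[nxt]] <- c(ni, nj)
    heights[nxt] <- bestd / 2
    si <- sizes[i]; sj <- sizes[j]
    newrow <- (si * D[i, ] + sj * D[j, ]) / (si + sj)
    D[i, ] <- newrow; D[, i] <- newrow; D[i, i] <- 0
    D <- D[-j, -j, drop = FALSE]
    nodes[i] <- nxt; sizes[i] <- si + sj
    nodes <- nodes[-j]; sizes <- sizes[-j]
    nxt <- nxt + 1L
  }
  rt <- list(nleaf = n, labels = labs, parent = parent, children = children,
             root = nodes[1])
  rtToPhylo(rt, heights)
}

# ---- clock least squares ----------------------------------------------

#' Clock least-squares fit of a fixed topology
#'
#' Optimizes the node heights of a given rooted binary topology to minimize
#' the weighted least-squares mismatch
#' `sum_{i<j} (d_ij - t_ij)^2 / d_ij^power` between the matrix and the
#' ultrametric path lengths `t_ij` (pairs with `d_ij = 0` get weight 1).
#' Heights are found exactly: each internal node's unconstrained optimum is
#' the weighted mean of `d/2` over the pairs it joins, projected onto the
#' constraint `h(parent) >= h(child) >= 0` by isotonic regression on the
#' tree order.
#'
#' @param topology rooted binary `phylo` whose tips match `labels(dm)`.
#' @param dm a [DissimilarityMatrix-class].
#' @param power weighting exponent (2 = Fitch-Margoliash convention).
#' @return list with `tree` (ultrametric `phylo`) and `score`.
#' @export
clockFit <- function(topology, dm, power = 2) {
  .checkDM(dm, 3L)
  labs <- labels(dm)
  if (!setequal(topology$tip.label, labs))
    stop("topology tips must match matrix labels")
  D <- as.matrix(dm)
  # map tree tip order onto matrix order
  rt <- rtFromPhylo(topology)
  perm <- match(rt$labels, labs)
  D <- D[perm, perm, drop = FALSE]
  W <- ifelse(D == 0, 1, 1 / D^power)
  diag(W) <- 0
  WD <- W * D; WD2 <- WD * D
  fit <- rtClockFit(rt, D, W, WD, WD2)
  list(tree = rtToPhylo(rt, fit$heights), score = fit$score)
}

#' Clock-constrained Fitch-Margoliash least-squares tree
#'
#' Reimplementation of the classic clock-constrained weighted
#' least-squares ("Kitsch") approach: starting from the UPGMA topology,
#' nearest-neighbor-interchange hill climbing with exact per-topology
#' height optimization (see [clockFit]), until no interchange improves the
#' fit. All branch lengths are non-negative by construction and the result
#' is exactly ultrametric.
#'
#' @param dm a [DissimilarityMatrix-class] with at least 3 taxa.
#' @param power weighting exponent of the least squares (default 2).
#' @param maxNni cap on accepted interchange moves.
#' @param restarts number of additional hill climbs from random starting
#'   topologies (uses the session RNG); the default 1 searches from the
#'   UPGMA start only.
#' @return list with `tree` (rooted ultrametric `phylo`), `score` (final
#'   weighted least-squares fit), `startScore` (fit of the UPGMA start)
#'   and `nniMoves` (accepted interchanges).
#' @export
fmClockTree <- function(dm, power = 2, maxNni = 200L, restarts = 1L) {
  .checkDM(dm, 3L)
  labs <- labels(dm)
  D0 <- as.matrix(dm)
  if (any(D0 < 0)) stop("matrix entries must be non-negative")
  starts <- list(rtFromPhylo(upgmaTree(dm)))
  if (restarts > 1L) {
    for (r in seq_len(restarts - 1L)) {
      rnd <- ape::rtree(length(labs), rooted = TRUE, br = NULL)
      rnd$tip.label <- sample(labs)
      starts[[r + 1L]] <- rtFromPhylo(rnd)
    }
  }
  bestAll <- NULL
  startScore <- NA_real_
  totMoves <- 0L
  for (si in seq_along(starts)) {
    rt <- starts[[si]]
    perm <- match(rt$labels, labs)
    D <- D0[perm, perm, drop = FALSE]
    W <- ifelse(D == 0, 1, 1 / D^power); diag(W) <- 0
    WD <- W * D; WD2 <- WD * D
    fit <- rtClockFit(rt, D, W, WD, WD2)
    if (si == 1L) startScore <- fit$score
    moves <- 0L
    repeat {
      if (moves >= maxNni) break
      nbs <- rtNniNeighbors(rt)
      bestScore <- fit$score
      bestIdx <- 0L
      bestFit <- NULL
      for (k in seq_along(nbs)) {
        f <- rtClockFit(nbs[[k]], D, W, WD, WD2)
        if (f$score < bestScore - 1e-12 * (1 + abs(bestScore))) {
          bestScore <- f$score; bestIdx <- k; bestFit <- f
        }
      }
      if (bestIdx == 0L) break
      rt <- nbs[[bestIdx]]
      fit <- bestFit
      moves <- moves + 1L
    }
    totMoves <- totMoves + moves
    if (is.null(bestAll) || fit$score < bestAll$score - 1e-12)
      bestAll <- list(rt = rt, score = fit$score, heights = fit$heights)
  }
  list(tree = rtToPhylo(bestAll$rt, bestAll$heights),
       score = bestAll$score, startScore = startScore, nniMoves = totMoves)
}

# ---- neighbor joining --------------------------------------------------

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei agglomeration with the Q criterion; ties are broken
#' by the lowest label-index pair. Negative branch-length estimates are
#' clamped to 0 with the deficit transferred to the sister branch, so all
#' branch lengths are non-negative. On an exactly additive matrix the tree
#' reproduces every pairwise distance.
#'
#' @param dm a [DissimilarityMatrix-class] with at least 3 taxa.
#' @return an unrooted `phylo` (trifurcating root node).
#' @export
neighborJoiningTree <- function(dm) {
  .checkDM(dm, 3L)
  labs <- labels(dm)
  n <- length(labs)
  D <- as.matrix(dm)
  nodes <- seq_len(n)
  m <- 2L * n - 2L
  parent <- rep(NA_integer_, m)
  children <- vector("list", m)
  elen <- rep(NA_real_, m)            # length of edge above each node
  nxt <- n + 1L
  while (length(nodes) > 3L) {
    k <- length(nodes)
    r <- rowSums(D)
    best <- c(1L, 2L); bestq <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      q <- (k - 2) * D[i, j] - r[i] - r[j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (k - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- D[i, j]; bi <- 0 }        # clamp, deficit to sister
    if (bj < 0) { bi <- D[i, j]; bj <- 0 }
    ni <- nodes[i]; nj <- nodes[j]
    parent[c(ni, nj)] <- nxt
    children[[nxt]] <- c(ni, nj)
    elen[ni] <- bi; elen[nj] <- bj
    newrow <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D[i, ] <- newrow; D[, i] <- newrow; D[i, i] <- 0
    D <- D[-j, -j, drop = FALSE]
    nodes[i] <- nxt
    nodes <- nodes[-j]
    nxt <- nxt + 1L
  }
  # final join of three nodes at an unresolved (trifurcating) center
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  center <- nxt
  parent[nodes] <- center
  children[[center]] <- nodes
  elen[nodes] <- pmax(c(b1, b2, b3), 0)
  rt <- list(nleaf = n, labels = labs, parent = parent[seq_len(center)],
             children = c(children[seq_len(center - 1L)], list(nodes)),
             root = center)
  # build phylo from edge lengths (not heights)
  newid <- rep(NA_integer_, center)
  newid[seq_len(n)] <- seq_len(n)
  nxt2 <- n + 1L
  stack <- center; pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    pre <- c(pre, v)
    if (length(rt$children[[v]])) {
      newid[v] <- nxt2; nxt2 <- nxt2 + 1L
      stack <- c(stack, rev(rt$children[[v]]))
    }
  }
  edges <- matrix(0L, 0, 2); len <- numeric(0)
  for (v in pre) for (ch in rt$children[[v]]) {
    edges <- rbind(edges, c(newid[v], newid[ch]))
    len <- c(len, elen[ch])
  }
  phy <- list(edge = edges, edge.length = len, tip.label = labs,
              Nnode = nxt2 - n - 1L)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

# ---- Newick serialization ---------------------------------------------

#' Read and write Newick trees
#'
#' Wrappers over ape's Newick parser/serializer. `writeNewick` writes (or
#' returns) the tree with branch lengths at 6 significant digits;
#' `readNewick` accepts a file path or a literal Newick string.
#'
#' @param tree a `phylo`.
#' @param path output file; when `NULL` the Newick string is returned.
#' @param x file path or Newick string.
#' @return `writeNewick`: the path (invisibly) or the Newick string;
#'   `readNewick`: a `phylo`.
#' @examples
#' t <- readNewick("((A:1,B:1):1,C:2);")
#' writeNewick(t)
#' @export
writeNewick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 6)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(x) {
  tr <- if (length(x) == 1L && !grepl("\\(", x) && file.exists(x))
    tryCatch(ape::read.tree(x), error = function(e) NULL)
  else
    tryCatch(ape::read.tree(text = x), error = function(e) NULL)
  if (is.null(tr)) stop("malformed Newick input")
  tr
}

# ---- cluster extraction ------------------------------------------------

# height of every node above the leaf level: max path length to a
# descendant leaf (equals the clock height for ultrametric trees)
nodeHeights <- function(tree) {
  n <- length(tree$tip.label)
  m <- n + tree$Nnode
  h <- rep(0, m)
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    h[p] <- max(h[p], h[ch] + po$edge.length[k])
  }
  h
}

#' Cut a rooted tree into leaf clusters
#'
#' Cuts all branches crossing a height (distance above the leaf level), or
#' chooses the height yielding `k` clusters (between the k-th and
#' (k-1)-th highest internal-node heights, i.e. dendrogram `cutree`
#' semantics). Exactly one of `height`/`k` must be given. Singleton blocks
#' are flagged as outliers.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param height cut height (same units as branch lengths).
#' @param k requested number of clusters (`1 <= k <=` number of leaves).
#' @return data.frame with columns `leaf`, `cluster` (integers numbered by
#'   first appearance in `tree$tip.label`) and `singleton`.
#' @export
extractClusters <- function(tree, height = NULL, k = NULL) {
  if (!ape::is.rooted(tree)) stop("a rooted tree is required")
  if (is.null(height) == is.null(k))
    stop("give exactly one of 'height' or 'k'")
  n <- length(tree$tip.label)
  h <- nodeHeights(tree)
  root <- n + 1L
  if (!is.null(k)) {
    if (k > n) stop("k must not exceed the number of leaves (", n, ")")
    if (k < 1L) stop("k must be at least 1")
    H <- sort(h[(n + 1L):(n + tree$Nnode)], decreasing = TRUE)
    height <- if (k == 1L) h[root]
              else if (k - 1L < length(H)) (H[k - 1L] + H[k]) / 2
              else H[length(H)] / 2
  }
  parent <- rep(NA_integer_, n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  isClusterRoot <- function(v)
    h[v] <= height && (is.na(parent[v]) || h[parent[v]] > height)
  roots <- which(vapply(seq_len(n + tree$Nnode), isClusterRoot, logical(1)))
  # leaves below each cluster root
  below <- vector("list", n + tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  for (v in seq_len(n)) below[[v]] <- v
  for (kk in seq_len(nrow(po$edge))) {
    p <- po$edge[kk, 1]; ch <- po$edge[kk, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  cl <- rep(NA_integer_, n)
  for (r in roots) cl[below[[r]]] <- r
  # renumber clusters by smallest member tip index
  firsts <- vapply(split(seq_len(n), cl), min, integer(1))
  ord <- rank(firsts)
  cl <- ord[match(cl, as.integer(names(firsts)))]
  if (!is.null(k) && length(unique(cl)) != k)
    warning("tied node heights: obtained ", length(unique(cl)),
            " clusters instead of ", k)
  sizes <- table(cl)
  data.frame(leaf = tree$tip.label, cluster = as.integer(cl),
             singleton = as.integer(sizes[as.character(cl)]) == 1L)
}

# ---- Robinson-Foulds ---------------------------------------------------

# canonical nontrivial bipartitions of an (implicitly unrooted) tree
treeSplits <- function(tree) {
  n <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  ref <- labs[1]
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + tree$Nnode)
  for (v in seq_len(n)) below[[v]] <- tree$tip.label[v]
  keys <- character(0)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
    side <- below[[ch]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (ref %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Number of nontrivial bipartitions present in exactly one of the two
#' trees (unrooted RF); both trees must carry the identical leaf set.
#'
#' @param treeA,treeB `phylo` objects on the same leaves.
#' @return non-negative integer.
#' @export
robinsonFoulds <- function(treeA, treeB) {
  if (!setequal(treeA$tip.label, treeB$tip.label)) {
    onlyA <- setdiff(treeA$tip.label, treeB$tip.label)
    onlyB <- setdiff(treeB$tip.label, treeA$tip.label)
    stop("leaf sets differ; only in A: {", paste(onlyA, collapse = ", "),
         "}, only in B: {", paste(onlyB, collapse = ", "), "}")
  }
  sa <- treeSplits(treeA)
  sb <- treeSplits(treeB)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Test whether a rooted tree is ultrametric
#'
#' All root-to-leaf path lengths equal within `tol`.
#'
#' @param tree rooted `phylo`.
#' @param tol absolute tolerance.
#' @return logical.
#' @export
isUltrametricTree <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)
  n <- length(tree$tip.label)
  diff(range(depths[seq_len(n)])) <= tol
}
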