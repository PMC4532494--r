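# Synthetic benchmark generator: families of related Ca-trace "domains"
# diverged along a known guide tree, so that every pipeline stage is
# testable against a ground-truth topology. The template geometry loosely
# mimics an eight-stranded antiparallel beta-barrel: straight strand
# segments on a cylinder joined by short loops, deformed by a smooth
# per-seed displacement field and re-stepped to an exact 3.8 A virtual
# bond length.

# evaluate `code` under a fixed seed without disturbing the caller's RNG
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# bridge two points with k intermediates, all steps exactly `step` long,
# bulging along unit vector w
.loopBridge <- function(p, q, k, w, step = 3.8) {
  u <- q - p; L <- sqrt(sum(u^2)); u <- u / L
  w <- w - sum(w * u) * u
  w <- w / sqrt(sum(w^2))
  if (k == 1L) {
    h <- sqrt(max(step^2 - (L / 2)^2, 0.01))
    return(matrix(p + (L / 2) * u + h * w, 1, 3))
  }
  a <- (L - step) / 2
  h <- sqrt(max(step^2 - a^2, 0.01))
  rbind(p + a * u + h * w, q - a * u + h * w)
}

#' Generate a synthetic template domain
#'
#' Builds a self-avoiding Cα trace of `length` residues: eight straight
#' strand segments placed antiparallel on a cylinder, joined by short
#' loops, then deformed by a smooth seed-specific sinusoidal displacement
#' field and re-stepped so every consecutive Cα-Cα distance is exactly
#' 3.8 Angstrom. The amino-acid sequence is uniform over the 20 standard
#' residues. Fully deterministic given `seed`.
#'
#' @param length number of residues (>= 20).
#' @param seed integer seed.
#' @param id domain label (default `"template<seed>"`).
#' @return a [DomainStructure-class].
#' @examples
#' d <- makeTemplate(160, seed = 7)
#' range(sqrt(rowSums(diff(caCoords(d))^2)))  # all 3.8
#' @export
makeTemplate <- function(length, seed, id = paste0("template", seed)) {
  stopifnot(length >= 20L)
  withSeed(seed, {
    step <- 3.8
    loopLen <- if (length >= 31L) 2L else 1L
    nLoopRes <- 7L * loopLen
    strandTotal <- length - nLoopRes
    base <- strandTotal %/% 8L
    rem <- strandTotal %% 8L
    slen <- rep(base, 8L)
    if (rem > 0L) slen[sample(8L, rem)] <- base + 1L
    radius <- if (loopLen == 2L) runif(1, 8.5, 10) else runif(1, 7.5, 8.2)
    rjit <- runif(8L, -0.4, 0.4)
    theta <- 2 * pi * (0:7) / 8
    raw <- NULL
    zend <- 0
    for (s in 1:8) {
      r <- radius + rjit[s]
      dirz <- if (s %% 2L == 1L) 1 else -1
      z0 <- if (s == 1L) 0 else zend
      z <- z0 + step * dirz * (seq_len(slen[s]) - 1L)
      pts <- cbind(r * cos(theta[s]), r * sin(theta[s]), z)
      if (s > 1L) {
        p <- raw[nrow(raw), ]; q <- pts[1, ]
        mid <- (p + q) / 2
        w <- c(mid[1], mid[2], 0)
        if (sqrt(sum(w^2)) < 1e-6) w <- c(1, 0, 0)
        w <- w / sqrt(sum(w^2))          # bulge radially outward
        raw <- rbind(raw, .loopBridge(p, q, loopLen, w, step))
      }
      raw <- rbind(raw, pts)
      zend <- z[slen[s]]
    }
    # smooth per-seed deformation, then re-step to exact bond length
    n <- nrow(raw)
    for (attempt in 1:20) {
      amp <- runif(3, 1.0, 2.0)
      lam <- runif(3, 15, 35)
      phi <- runif(3, 0, 2 * pi)
      idx <- seq_len(n)
      disp <- cbind(amp[1] * sin(2 * pi * idx / lam[1] + phi[1]),
                    amp[2] * sin(2 * pi * idx / lam[2] + phi[2]),
                    amp[3] * sin(2 * pi * idx / lam[3] + phi[3]))
      target <- raw + disp
      coords <- matrix(0, n, 3)
      coords[1, ] <- target[1, ]
      for (i in 2:n) {
        d <- target[i, ] - coords[i - 1, ]
        coords[i, ] <- coords[i - 1, ] + step * d / sqrt(sum(d^2))
      }
      # self-avoidance: non-neighbours at least 2 A apart
      dmin <- min(as.matrix(stats::dist(coords))[
        upper.tri(diag(n)) & abs(row(diag(n)) - col(diag(n))) > 1])
      if (dmin >= 2.0) break
    }
    new("DomainStructure", id = id, coords = coords,
        aa = sample(.AA20, n, replace = TRUE), resno = seq_len(n))
  })
}

#' Construct a synthetic family specification
#'
#' @param guideTree rooted `phylo` with branch lengths in divergence units.
#' @param templateLength template size in residues.
#' @param noiseSigma Brownian coordinate noise: per-coordinate Gaussian
#'   s.d. `noiseSigma * sqrt(l)` on a branch of length `l` (Angstrom), so
#'   expected squared deviation is additive along paths.
#' @param indelRate expected single-residue deletions per unit branch
#'   length (deletions only; indices stay monotone).
#' @param substitutionRate expected residue substitutions per unit branch
#'   length.
#' @param seed integer RNG seed.
#' @return a [SyntheticTreeSpec-class].
#' @export
syntheticTreeSpec <- function(guideTree, templateLength = 160L,
                              noiseSigma = 0.3, indelRate = 0.5,
                              substitutionRate = 8, seed = 1L) {
  new("SyntheticTreeSpec", guideTree = guideTree,
      templateLength = as.integer(templateLength),
      noiseSigma = noiseSigma, indelRate = indelRate,
      substitutionRate = substitutionRate, seed = as.integer(seed))
}

#' Evolve a template along a guide tree
#'
#' The root carries the template built by [makeTemplate]. Along each branch
#' of length `l`, in order: (1) i.i.d. Gaussian coordinate noise with
#' per-coordinate s.d. `noiseSigma * sqrt(l)`; (2) `Poisson(indelRate*l)`
#' single-residue deletions at uniform positions; (3)
#' `Poisson(substitutionRate*l)` substitutions at uniform positions (a
#' position may be hit more than once), each to a uniformly drawn different
#' residue. Traversal is preorder with children in stored order, so output
#' is fully reproducible from the spec's seed.
#'
#' @param spec a [SyntheticTreeSpec-class].
#' @return named list of [DomainStructure-class], one per guide-tree leaf.
#' @export
evolveAlongTree <- function(spec) {
  stopifnot(is(spec, "SyntheticTreeSpec"))
  tmpl <- makeTemplate(spec@templateLength, seed = spec@seed)
  phy <- ape::reorder.phylo(spec@guideTree, "cladewise")
  rt <- rtFromPhylo(phy)
  blen <- rep(NA_real_, length(rt$parent))
  blen[phy$edge[, 2]] <- phy$edge.length
  out <- list()
  withSeed(spec@seed + 1L, {
    evolveNode <- function(v, coords, aa, resno) {
      if (!is.na(rt$parent[v])) {
        l <- blen[v]
        n <- nrow(coords)
        if (l > 0) {
          coords <- coords + matrix(rnorm(3L * n, 0,
                                          spec@noiseSigma * sqrt(l)), n, 3L)
          ndel <- rpois(1L, spec@indelRate * l)
          if (ndel > 0L) {
            if (n - ndel < 20L)
              stop("deletions reduce a leaf below 20 residues; ",
                   "lower indelRate or shorten the tree")
            del <- sample(n, ndel)
            coords <- coords[-del, , drop = FALSE]
            aa <- aa[-del]; resno <- resno[-del]
            n <- n - ndel
          }
          nsub <- rpois(1L, spec@substitutionRate * l)
          if (nsub > 0L) {
            pos <- sample(n, nsub, replace = TRUE)
            for (p in pos) aa[p] <- sample(setdiff(.AA20, aa[p]), 1L)
          }
        }
      }
      kids <- rt$children[[v]]
      if (!length(kids)) {
        lab <- rt$labels[v]
        out[[lab]] <<- new("DomainStructure", id = lab, coords = coords,
                           aa = aa, resno = resno)
      } else {
        for (k in kids) evolveNode(k, coords, aa, resno)
      }
    }
    evolveNode(rt$root, tmpl@coords, tmpl@aa, tmpl@resno)
  })
  out[phy$tip.label]
}

#' Balanced ultrametric guide tree
#'
#' Fully balanced rooted binary clock tree (`nLeaves` must be a power of
#' two) with total root-to-leaf depth `depth`, split equally across levels.
#' Leaves are labelled `t1..tN`.
#'
#' @param nLeaves number of leaves (power of 2).
#' @param depth root-to-leaf path length in divergence units.
#' @return a rooted ultrametric `phylo`.
#' @export
balancedClockTree <- function(nLeaves, depth = 1) {
  lv <- log2(nLeaves)
  if (lv != round(lv)) stop("nLeaves must be a power of 2")
  bl <- depth / lv
  build <- function(ids) {
    if (length(ids) == 1L) return(sprintf("t%d:%g", ids, bl))
    half <- length(ids) / 2
    sprintf("(%s,%s):%g", build(ids[seq_len(half)]),
            build(ids[-seq_len(half)]), bl)
  }
  if (nLeaves == 1L) stop("need at least 2 leaves")
  half <- nLeaves / 2
  txt <- sprintf("(%s,%s);", build(seq_len(half)),
                 build(seq_len(nLeaves)[-seq_len(half)]))
  readNewick(txt)
}

#' Random ultrametric guide tree
#'
#' Coalescent topology rescaled to total depth `depth`; labels `t1..tN`.
#' Uses the session RNG (seed with [withSeed] or `set.seed`).
#'
#' @param nLeaves number of leaves.
#' @param depth root-to-leaf depth in divergence units.
#' @return a rooted ultrametric `phylo`.
#' @export
randomClockTree <- function(nLeaves, depth = 1) {
  phy <- ape::rcoal(nLeaves)
  h <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * depth / h
  phy
}

#' Write a synthetic family to disk
#'
#' Emits one Cα-only PDB per domain, a FASTA of all sequences, the guide
#' tree in Newick (when given) and a manifest TSV (`id`, `path`, `chain`,
#' `range`) consumable by [runPipeline].
#'
#' @param structures named list of [DomainStructure-class].
#' @param dir output directory (created if needed).
#' @param guideTree optional `phylo` written as `guide_tree.nwk`.
#' @return path of the manifest file, invisibly.
#' @export
writeSyntheticFamily <- function(structures, dir, guideTree = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(structures, domainId, character(1))
  paths <- file.path(dir, paste0(ids, ".pdb"))
  for (i in seq_along(structures))
    writeDomainPDB(structures[[i]], paths[i])
  writeFasta(structures, file.path(dir, "sequences.fasta"))
  if (!is.null(guideTree))
    writeNewick(guideTree, file.path(dir, "guide_tree.nwk"))
  manifest <- data.frame(id = ids, path = paths, chain = "A", range = "")
  mf <- file.path(dir, "manifest.tsv")
  write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mf)
}
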