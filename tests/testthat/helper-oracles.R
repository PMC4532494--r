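# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force rotation grids, exhaustive
# alignment/topology enumeration, and a QP solver for clock heights.

# ---- rotation-grid RMSD oracle -----------------------------------------
# Minimum RMSD over proper rotations found by an Euler-angle grid search,
# coarse-to-fine (final step well below 0.5 degrees). Translation is
# optimal at centred coordinates.
gridMinRmsd <- function(A, B) {
  Ac <- scale(A, scale = FALSE)
  Bc <- scale(B, scale = FALSE)
  M <- t(Ac) %*% Bc                     # rmsd^2 = (cst - 2 tr(M R')) / n
  cst <- sum(Ac^2) + sum(Bc^2)
  n <- nrow(A)
  rot <- function(a, b, c) {
    Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz2 <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(a, b, c) {
    R <- rot(a, b, c)
    cst - 2 * sum(M * R)
  }
  best <- c(0, 0, 0); bestv <- obj(0, 0, 0)
  step <- 10 * pi / 180
  for (a in seq(0, 2 * pi, by = step)) for (b in seq(0, pi, by = step))
    for (c in seq(0, 2 * pi, by = step)) {
      v <- obj(a, b, c)
      if (v < bestv) { bestv <- v; best <- c(a, b, c) }
    }
  while (step > 0.002 * pi / 180) {
    repeat {                      # pattern search: walk at this resolution
      improved <- FALSE
      for (da in c(-step, 0, step)) for (db in c(-step, 0, step))
        for (dc in c(-step, 0, step)) {
          v <- obj(best[1] + da, best[2] + db, best[3] + dc)
          if (v < bestv - 1e-14) {
            bestv <- v; best <- best + c(da, db, dc); improved <- TRUE
          }
        }
      if (!improved) break
    }
    step <- step / 2
  }
  sqrt(max(bestv, 0) / n)
}

# ---- exhaustive rooted-topology enumeration ----------------------------
enumRootedTopologies <- function(labs) {
  if (length(labs) == 1L) return(list(labs[1]))
  trees <- enumRootedTopologies(labs[-length(labs)])
  leaf <- labs[length(labs)]
  attachAll <- function(tr) {
    if (!is.list(tr)) return(list())
    res <- list()
    for (i in 1:2) {
      sub <- tr[[i]]
      t1 <- tr; t1[[i]] <- list(sub, leaf)
      res <- c(res, list(t1))
      for (r in attachAll(sub)) { t2 <- tr; t2[[i]] <- r; res <- c(res, list(t2)) }
    }
    res
  }
  out <- list()
  for (tr in trees) out <- c(out, attachAll(tr), list(list(tr, leaf)))
  out
}

topologyNewick <- function(tr) {
  f <- function(x) if (!is.list(x)) x else
    paste0("(", f(x[[1]]), ",", f(x[[2]]), ")")
  paste0(f(tr), ";")
}

# best clock least-squares score over all rooted topologies
exhaustiveClockScore <- function(dm, power = 2) {
  best <- Inf
  for (tr in enumRootedTopologies(labels(dm))) {
    s <- clockFit(readNewick(topologyNewick(tr)), dm, power = power)$score
    if (s < best) best <- s
  }
  best
}

# ---- QP oracle for clock heights on a fixed topology -------------------
# Solves min sum w (d - 2 h_lca)^2 s.t. h_child <= h_parent, h >= 0 with
# pracma's quadprog; returns the optimal score.
qpClockScore <- function(topology, dm, power = 2) {
  labs <- labels(dm)
  D <- as.matrix(dm)
  n <- length(labs)
  W <- ifelse(D == 0, 1, 1 / D^power); diag(W) <- 0
  ints <- (n + 1):(n + topology$Nnode)
  mr <- ape::mrca(topology)
  H <- rep(0, length(ints)); f <- rep(0, length(ints)); cst <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    li <- match(topology$tip.label[i], labs)
    lj <- match(topology$tip.label[j], labs)
    d <- D[li, lj]; w <- W[li, lj]
    v <- match(mr[i, j], ints)
    H[v] <- H[v] + 8 * w
    f[v] <- f[v] - 4 * w * d
    cst <- cst + w * d^2
  }
  parent <- rep(NA_integer_, n + topology$Nnode)
  parent[topology$edge[, 2]] <- topology$edge[, 1]
  A <- NULL; b <- NULL
  for (v in ints) if (!is.na(parent[v])) {
    row <- rep(0, length(ints))
    row[match(v, ints)] <- 1
    row[match(parent[v], ints)] <- -1
    A <- rbind(A, row); b <- c(b, 0)
  }
  sol <- pracma::quadprog(diag(H, nrow = length(ints)), f, A = A, b = b,
                          lb = rep(0, length(ints)))
  as.numeric(cst + 0.5 * t(sol$xmin) %*% diag(H, nrow = length(ints)) %*%
               sol$xmin + sum(f * sol$xmin))
}

# ---- exhaustive global-alignment score ---------------------------------
bruteAlignScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb))
      best <- max(best, rec(i + 1, j + 1) +
                    if (ca[i] == cb[j]) match else mismatch)
    if (i <= length(ca)) best <- max(best, rec(i + 1, j) + gap)
    if (j <= length(cb)) best <- max(best, rec(i, j + 1) + gap)
    best
  }
  rec(1, 1)
}

# ---- misc helpers ------------------------------------------------------
randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y)),
        c(2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x)),
        c(2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)))
}

randomDissimilarity <- function(n, lo = 1, hi = 10) {
  labs <- paste0("t", seq_len(n))
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2, lo, hi)
  v <- v + t(v)
  dimnames(v) <- list(labs, labs)
  DissimilarityMatrix(v)
}

rigidCopy <- function(structure, id = "copy") {
  R <- randomRotation()
  t <- rnorm(3, 0, 10)
  out <- structure
  out@id <- id
  out@coords <- structure@coords %*% t(R) +
    matrix(t, nrow(structure@coords), 3, byrow = TRUE)
  out
}

perturbedCopy <- function(structure, sigma, id = "noisy") {
  out <- structure
  out@id <- id
  out@coords <- structure@coords +
    matrix(rnorm(length(structure@coords), 0, sigma),
           nrow(structure@coords), 3)
  out
}

# a small PDB file exercising altloc / missing-Ca / unknown-residue rules
writeFixturePDB <- function(path) {
  rec <- function(serial, name, alt, res, resno, x, y, z, occ) {
    paste0("ATOM  ", formatC(serial, width = 5), " ", name, alt,
           formatC(res, width = 3), " A", formatC(resno, width = 4),
           "    ", sprintf("%8.3f%8.3f%8.3f%6.2f%6.2f", x, y, z, occ, 0))
  }
  lines <- c(
    rec(1, " CA ", " ", "ALA", 1, 0.0, 0.0, 0.0, 1.0),
    rec(2, " CA ", "A", "GLY", 2, 3.8, 0.0, 0.0, 0.4),
    rec(3, " CA ", "B", "GLY", 2, 3.8, 0.5, 0.0, 0.6),
    rec(4, " N  ", " ", "SER", 3, 7.0, 1.0, 0.0, 1.0),  # no Ca: skipped
    rec(5, " CA ", " ", "TRP", 4, 7.6, 0.0, 0.0, 1.0),
    rec(6, " CA ", " ", "XYZ", 5, 11.4, 0.0, 0.0, 1.0), # unknown residue
    rec(7, " CA ", " ", "LEU", 6, 15.2, 0.0, 0.0, 1.0),
    "END")
  writeLines(lines, path)
  path
}
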