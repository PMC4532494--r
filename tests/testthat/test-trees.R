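ultrametricFromTree <- function(tree) {
  cc <- ape::cophenetic.phylo(tree)
  DissimilarityMatrix(cc[order(rownames(cc)), order(colnames(cc))])
}

test_that("UPGMA reproduces hand-computed and simulator ground truth", {
  # 2 taxa: single cherry with pendant branches d/2
  m2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgmaTree(DissimilarityMatrix(m2))
  expect_equal(sort(t2$edge.length), c(2, 2))
  # 3 taxa, d(A,B)=2, d(A,C)=d(B,C)=6: ((A,B),C), pendants 1, root height 3
  m3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgmaTree(DissimilarityMatrix(m3))
  expect_equal(writeNewick(t3), "((A:1,B:1):2,C:3);")
  # exactly ultrametric 5-taxon input is recovered with exact heights
  set.seed(1)
  truth <- randomClockTree(5, depth = 2)
  dm <- ultrametricFromTree(truth)
  rec <- upgmaTree(dm)
  expect_equal(robinsonFoulds(rec, truth), 0)
  cc <- ape::cophenetic.phylo(rec)[labels(dm), labels(dm)]
  expect_equal(cc, as.matrix(dm), tolerance = 1e-9)
  expect_true(isUltrametricTree(rec))
})

test_that("clock least squares fits ultrametric input perfectly", {
  set.seed(2)
  truth <- randomClockTree(6, depth = 1.5)
  dm <- ultrametricFromTree(truth)
  fit <- fmClockTree(dm)
  expect_equal(fit$score, 0, tolerance = 1e-12)
  cc <- ape::cophenetic.phylo(fit$tree)[labels(dm), labels(dm)]
  expect_equal(cc, as.matrix(dm), tolerance = 1e-6)
  expect_true(isUltrametricTree(fit$tree))
  expect_true(all(fit$tree$edge.length >= 0))
})

test_that("per-topology height optimization matches a QP solver", {
  skip_if_not_installed("pracma")
  set.seed(3)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    dm <- randomDissimilarity(n)
    topo <- ape::rtree(n, tip.label = sample(labels(dm)))
    expect_equal(clockFit(topo, dm)$score, qpClockScore(topo, dm),
                 tolerance = 1e-8)
  }
})

test_that("clock search matches exhaustive enumeration on small problems", {
  set.seed(4)
  for (rep in 1:3) for (n in 4:5) {
    dm <- randomDissimilarity(n)
    fit <- fmClockTree(dm)
    expect_equal(fit$score, exhaustiveClockScore(dm), tolerance = 1e-9)
    expect_lte(fit$score, fit$startScore + 1e-12)   # never worse than UPGMA
  }
})

test_that("perturbed clock matrices still yield the true topology", {
  set.seed(5)
  truth <- readNewick("((A:1,B:1):2,(C:2,D:2):1);")
  d0 <- ape::cophenetic.phylo(truth)
  for (rep in 1:5) {
    pert <- d0 * matrix(runif(16, 0.99, 1.01), 4)
    pert <- (pert + t(pert)) / 2; diag(pert) <- 0
    dm <- DissimilarityMatrix(pert)
    fit <- fmClockTree(dm)
    expect_equal(robinsonFoulds(fit$tree, truth), 0)
    expect_equal(fit$score, exhaustiveClockScore(dm), tolerance = 1e-9)
  }
})

test_that("neighbor joining recovers additive matrices exactly", {
  madd <- matrix(c(0, 5, 9, 10, 5, 0, 10, 11, 9, 10, 0, 7, 10, 11, 7, 0), 4,
                 dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tn <- neighborJoiningTree(DissimilarityMatrix(madd))
  cc <- ape::cophenetic.phylo(tn)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cc, madd, tolerance = 1e-9)
  # same topology as the reference implementation
  ref <- ape::nj(as.dist(madd))
  expect_equal(robinsonFoulds(tn, ref), 0)
  # larger random additive matrices
  set.seed(6)
  for (rep in 1:5) {
    truth <- ape::rtree(7)
    dmat <- ape::cophenetic.phylo(truth)
    dmat <- dmat[order(rownames(dmat)), order(colnames(dmat))]
    tn2 <- neighborJoiningTree(DissimilarityMatrix(dmat))
    cc2 <- ape::cophenetic.phylo(tn2)[rownames(dmat), colnames(dmat)]
    expect_equal(cc2, dmat, tolerance = 1e-9)
    expect_equal(robinsonFoulds(tn2, truth), 0)
  }
})

test_that("3-taxon neighbor joining uses the closed-form branch lengths", {
  m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tn <- neighborJoiningTree(DissimilarityMatrix(m))
  bl <- setNames(tn$edge.length, tn$tip.label[tn$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("NJ clamps negative branch estimates and stays deterministic", {
  # violated triangle inequality drives a closed-form branch negative
  m <- matrix(c(0, 2, 2, 2, 0, 5, 2, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tn <- neighborJoiningTree(DissimilarityMatrix(m))
  expect_true(all(tn$edge.length >= 0))
  # equidistant (star-like) matrix: ties resolved deterministically
  st <- matrix(4, 4, 4); diag(st) <- 0
  dimnames(st) <- list(LETTERS[1:4], LETTERS[1:4])
  t1 <- neighborJoiningTree(DissimilarityMatrix(st))
  t2 <- neighborJoiningTree(DissimilarityMatrix(st))
  expect_identical(writeNewick(t1), writeNewick(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("Newick serialization round-trips", {
  t3 <- readNewick("((A:1,B:1):1,C:2);")
  expect_equal(writeNewick(t3), "((A:1,B:1):1,C:2);")
  # SCOP-style labels survive verbatim
  td <- readNewick("((d1tvqa_:0.5,d1liba_:0.5):0.25,d2fr2a1:0.75);")
  expect_setequal(td$tip.label, c("d1tvqa_", "d1liba_", "d2fr2a1"))
  # random 20-leaf tree: read(write(t)) is isomorphic with equal path lengths
  set.seed(7)
  tr <- ape::rtree(20)
  back <- readNewick(writeNewick(tr))
  expect_equal(robinsonFoulds(back, tr), 0)
  expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-5)
  expect_error(readNewick("((A:1,B:1:2;"), "malformed")
})

test_that("cluster extraction honours k, height and singleton flags", {
  # 3 clear blocks, one of them a singleton
  m <- matrix(40, 5, 5)
  dimnames(m) <- list(letters[1:5], letters[1:5])
  m["a", "b"] <- m["b", "a"] <- 2
  m["c", "d"] <- m["d", "c"] <- 4
  m["a", "c"] <- m["c", "a"] <- m["a", "d"] <- m["d", "a"] <- 20
  m["b", "c"] <- m["c", "b"] <- m["b", "d"] <- m["d", "b"] <- 20
  diag(m) <- 0
  tr <- upgmaTree(DissimilarityMatrix(m))
  cl <- extractClusters(tr, k = 3)
  expect_equal(length(unique(cl$cluster)), 3L)
  blocks <- split(cl$leaf, cl$cluster)
  expect_true(any(vapply(blocks, function(b) setequal(b, c("a", "b")),
                         logical(1))))
  expect_true(any(vapply(blocks, function(b) setequal(b, c("c", "d")),
                         logical(1))))
  expect_equal(cl$singleton, cl$leaf == "e")
  # same partition from an explicit height cut
  clh <- extractClusters(tr, height = 5)
  expect_equal(clh$cluster, cl$cluster)
  # extremes
  expect_equal(length(unique(extractClusters(tr, k = 1)$cluster)), 1L)
  expect_equal(length(unique(extractClusters(tr, k = 5)$cluster)), 5L)
  expect_error(extractClusters(tr, k = 6), "exceed")
  expect_error(extractClusters(tr, k = 2, height = 1), "exactly one")
  expect_error(extractClusters(neighborJoiningTree(DissimilarityMatrix(m)),
                               k = 2), "rooted")
})

test_that("Robinson-Foulds equals the bipartition symmetric difference", {
  t1 <- readNewick("((A,B),(C,D));")
  t2 <- readNewick("((A,C),(B,D));")
  expect_equal(robinsonFoulds(t1, t1), 0)
  expect_equal(robinsonFoulds(t1, t2), 2)
  skip_if_not_installed("phangorn")
  set.seed(8)
  for (rep in 1:8) {
    a <- ape::rtree(10)
    b <- ape::rtree(10)
    expect_equal(robinsonFoulds(a, b),
                 phangorn::RF.dist(ape::unroot(a), ape::unroot(b)))
  }
  t3 <- readNewick("((A,B),(C,E));")
  expect_error(robinsonFoulds(t1, t3), "leaf sets differ")
})
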