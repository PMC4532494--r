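test_that("self- and rigid-copy alignments are exact and full length", {
  d <- makeTemplate(120, seed = 1)
  al <- iterativeAlign(d, d)
  expect_equal(nEquivalent(al), 120L)
  expect_equal(unname(alignedPairs(al)), cbind(1:120, 1:120))
  expect_lt(alignmentRmsd(al), 1e-8)
  expect_true(isConverged(al))
  set.seed(10)
  al2 <- iterativeAlign(d, rigidCopy(d))
  expect_equal(nEquivalent(al2), 120L)
  expect_lt(alignmentRmsd(al2), 1e-6)
})

test_that("alignment under isotropic noise matches its expected RMSD", {
  d <- makeTemplate(150, seed = 2)
  sigma <- 0.3
  rmsds <- neq <- numeric(5)
  set.seed(1)
  for (r in 1:5) {
    al <- iterativeAlign(d, perturbedCopy(d, sigma))
    rmsds[r] <- alignmentRmsd(al)
    neq[r] <- nEquivalent(al)
  }
  expect_true(all(neq >= 0.95 * 150))
  # expected per-atom displacement of isotropic 3-D Gaussian noise
  expect_gt(mean(rmsds), 0.8 * sigma * sqrt(3))
  expect_lt(mean(rmsds), 1.2 * sigma * sqrt(3))
})

test_that("alignment is near-symmetric in its arguments", {
  guide <- balancedClockTree(4, depth = 1)
  for (s in 1:3) {
    spec <- syntheticTreeSpec(guide, templateLength = 140, noiseSigma = 0.6,
                              indelRate = 1, seed = s)
    lv <- evolveAlongTree(spec)
    a <- lv[[1]]; b <- lv[[4]]        # most-diverged pair
    ab <- iterativeAlign(a, b)
    ba <- iterativeAlign(b, a)
    expect_lte(abs(nEquivalent(ab) - nEquivalent(ba)),
               0.02 * min(domainLength(a), domainLength(b)))
    expect_lte(abs(alignmentRmsd(ab) - alignmentRmsd(ba)), 0.05)
  }
})

test_that("expected RMSD rises and PFTE falls with noise level", {
  d <- makeTemplate(100, seed = 5)
  sigmas <- c(0.1, 0.5, 1.0, 1.5)
  set.seed(2)
  mrmsd <- mpfte <- numeric(length(sigmas))
  for (i in seq_along(sigmas)) {
    rs <- ps <- numeric(10)
    for (r in 1:10) {
      al <- iterativeAlign(d, perturbedCopy(d, sigmas[i]))
      rs[r] <- alignmentRmsd(al)
      ps[r] <- computePFTE(nEquivalent(al), 100, 100)
    }
    mrmsd[i] <- mean(rs); mpfte[i] <- mean(ps)
  }
  expect_true(all(diff(mrmsd) > 0))
  expect_true(all(diff(mpfte) <= 0))
})

test_that("every reported equivalence satisfies the cutoff after transform", {
  a <- makeTemplate(130, seed = 6)
  set.seed(4)
  bn <- perturbedCopy(a, 1.2)
  al <- iterativeAlign(a, bn, cutoff = 3.0)
  tr <- alignmentTransform(al)
  bt <- applyTransform(caCoords(bn), tr$rotation, tr$translation)
  p <- alignedPairs(al)
  d <- sqrt(rowSums((caCoords(a)[p[, 1], ] - bt[p[, 2], ])^2))
  expect_true(all(d <= 3.0 + 1e-9))
  # pairs are sequential and non-crossing
  expect_true(all(diff(p[, 1]) > 0) && all(diff(p[, 2]) > 0))
})

test_that("pairs with no usable seed come back maximally dissimilar", {
  mk <- function(id, seed) {
    set.seed(seed)
    new("DomainStructure", id = id,
        coords = matrix(runif(90, -100, 100), 30, 3),
        aa = sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 30, TRUE),
        resno = 1:30)
  }
  al <- iterativeAlign(mk("a", 1), mk("b", 2))
  expect_equal(nEquivalent(al), 0L)
  expect_true(isConverged(al))
  expect_true(is.na(alignmentRmsd(al)))
})

test_that("too-short structures are rejected", {
  mk <- function(n) new("DomainStructure", id = "x",
                        coords = cbind(1:n * 3.8, 0, 0),
                        aa = rep("A", n), resno = seq_len(n))
  expect_error(iterativeAlign(mk(5), mk(5)), "degenerate")
})

test_that("imported equivalences reproduce the direct Kabsch fit", {
  a <- makeTemplate(50, seed = 8)
  set.seed(9)
  b <- perturbedCopy(a, 0.5, id = "b")
  # diagonal import on identical structures gives rmsd 0
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("index_a\tindex_b", paste(0:49, 0:49, sep = "\t")), f)
  expect_lt(alignmentRmsd(importAlignment(f, a, a)), 1e-10)
  # 10-pair import equals kabschSuperpose on those coordinates exactly
  idx <- sort(sample(50, 10))
  writeLines(c("index_a\tindex_b", paste(idx - 1, idx - 1, sep = "\t")), f)
  imp <- importAlignment(f, a, b)
  ref <- kabschSuperpose(caCoords(a)[idx, ], caCoords(b)[idx, ])
  expect_equal(alignmentRmsd(imp), ref$rmsd, tolerance = 1e-12)
  # round trip through writeAlignmentTable preserves the alignment
  al <- iterativeAlign(a, b)
  writeAlignmentTable(al, f)
  back <- importAlignment(f, a, b)
  expect_equal(alignedPairs(back), alignedPairs(al))
  expect_equal(alignmentRmsd(back), alignmentRmsd(al), tolerance = 1e-9)
})

test_that("malformed equivalence files are rejected with line numbers", {
  a <- makeTemplate(50, seed = 8)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("index_a\tindex_b", "1\t2", "2\t1"), f)
  expect_error(importAlignment(f, a, a), "crossing")
  writeLines(c("index_a\tindex_b", "1\t99"), f)
  expect_error(importAlignment(f, a, a), "out-of-range")
  writeLines("index_a\tindex_b", f)
  expect_error(importAlignment(f, a, a), "empty")
})
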