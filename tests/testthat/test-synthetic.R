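test_that("templates are deterministic with exact virtual bond geometry", {
  d1 <- makeTemplate(160, seed = 7)
  d2 <- makeTemplate(160, seed = 7)
  expect_identical(caCoords(d1), caCoords(d2))
  expect_identical(domainSequence(d1), domainSequence(d2))
  steps <- sqrt(rowSums(diff(caCoords(d1))^2))
  expect_true(all(steps >= 3.7 & steps <= 3.9))
  # self-avoiding: non-neighbours at least 2 A apart
  dmat <- as.matrix(dist(caCoords(d1)))
  nonadj <- abs(row(dmat) - col(dmat)) > 1
  expect_gte(min(dmat[nonadj]), 2.0)
  # short templates are allowed down to 20 residues
  expect_equal(domainLength(makeTemplate(20, seed = 1)), 20L)
  expect_error(makeTemplate(10, seed = 1), "length >= 20")
})

test_that("different seeds give genuinely different folds", {
  rmsds <- vapply(1:20, function(i) {
    a <- makeTemplate(120, seed = i)
    b <- makeTemplate(120, seed = i + 1)
    kabschSuperpose(caCoords(a), caCoords(b))$rmsd
  }, numeric(1))
  expect_true(all(rmsds > 2))
})

test_that("null divergence returns identical leaves and an all-zero matrix", {
  guide <- balancedClockTree(4, depth = 1)
  spec <- syntheticTreeSpec(guide, templateLength = 60, noiseSigma = 0,
                            indelRate = 0, substitutionRate = 0, seed = 3)
  leaves <- evolveAlongTree(spec)
  expect_setequal(names(leaves), guide$tip.label)
  tmpl <- makeTemplate(60, seed = 3)
  for (lf in leaves) {
    expect_identical(caCoords(lf), caCoords(tmpl))
    expect_identical(domainSequence(lf), domainSequence(tmpl))
  }
  pr <- combn(4, 2)
  alns <- lapply(seq_len(ncol(pr)), function(k)
    iterativeAlign(leaves[[pr[1, k]]], leaves[[pr[2, k]]]))
  dm <- buildDissimilarityMatrix(sdmPairTable(alns, leaves))
  expect_true(all(as.matrix(dm) == 0))
})

test_that("Brownian noise accumulates additively along branches", {
  # two leaves, branch length l each, noise only: per-coordinate variance
  # 2 l sigma^2 between the leaves, so E[RMSD] ~ sigma * sqrt(3 * 2l)
  sigma <- 0.3; l <- 0.5
  guide <- balancedClockTree(2, depth = l)
  rmsds <- vapply(1:100, function(s) {
    sp <- syntheticTreeSpec(guide, templateLength = 80, noiseSigma = sigma,
                            indelRate = 0, substitutionRate = 0, seed = s)
    lv <- evolveAlongTree(sp)
    kabschSuperpose(caCoords(lv[[1]]), caCoords(lv[[2]]))$rmsd
  }, numeric(1))
  expected <- sigma * sqrt(3 * 2 * l)
  expect_gt(mean(rmsds), 0.9 * expected)
  expect_lt(mean(rmsds), 1.1 * expected)
})

test_that("generation is reproducible and respects the minimum length", {
  guide <- balancedClockTree(4, depth = 1)
  spec <- syntheticTreeSpec(guide, templateLength = 40, seed = 11)
  a <- evolveAlongTree(spec)
  b <- evolveAlongTree(spec)
  for (nm in names(a)) expect_identical(caCoords(a[[nm]]), caCoords(b[[nm]]))
  # massive deletion load must abort with advice
  hot <- syntheticTreeSpec(guide, templateLength = 25, indelRate = 50,
                           seed = 1)
  expect_error(evolveAlongTree(hot), "lower indelRate")
})

test_that("divergence separates within- from between-subtree pairs", {
  guide <- balancedClockTree(8, depth = 1)
  pl <- ape::cophenetic.phylo(guide)
  set.seed(12)
  agg <- matrix(0, 8, 8, dimnames = dimnames(pl))
  nseeds <- 5
  for (s in 1:nseeds) {
    sp <- syntheticTreeSpec(guide, templateLength = 120, seed = 100 + s)
    lv <- evolveAlongTree(sp)
    pr <- combn(8, 2)
    alns <- lapply(seq_len(ncol(pr)), function(k)
      iterativeAlign(lv[[pr[1, k]]], lv[[pr[2, k]]]))
    dm <- buildDissimilarityMatrix(sdmPairTable(alns, lv),
                                   labels = names(lv))
    agg[names(lv), names(lv)] <- agg[names(lv), names(lv)] + as.matrix(dm)
  }
  agg <- agg / nseeds
  near <- pl[upper.tri(pl)] < max(pl[upper.tri(pl)])   # within-subtree
  sdms <- agg[rownames(pl), colnames(pl)][upper.tri(pl)]
  expect_gt(mean(sdms[!near]), mean(sdms[near]))
})
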