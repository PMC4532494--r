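test_that("identity over structural equivalences counts matching residues", {
  d <- makeTemplate(80, seed = 1)
  al <- iterativeAlign(d, d)
  rec <- identityFromStructuralAlignment(al, d, d)
  expect_equal(rec$percent_identity, 100)
  expect_equal(rec$n_aligned, 80L)
  expect_false(rec$undefined)
  # controlled mismatch count: mutate 20 of 80 residues
  set.seed(2)
  b <- d; b@id <- "mut"
  pos <- sample(80, 20)
  for (p in pos) b@aa[p] <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                    d@aa[p])[1]
  al2 <- iterativeAlign(d, b)
  rec2 <- identityFromStructuralAlignment(al2, d, b)
  expect_equal(rec2$n_aligned, 80L)
  expect_equal(rec2$n_identical, 60L)
  expect_equal(rec2$percent_identity, 75)
  # symmetric in (a, b)
  al3 <- iterativeAlign(b, d)
  rec3 <- identityFromStructuralAlignment(al3, b, d)
  expect_equal(rec3$percent_identity, rec2$percent_identity)
  # empty alignment: 0% with undefined flag
  empty <- new("StructuralAlignment", idA = "x", idB = "y",
               pairs = matrix(integer(0), 0, 2), rotation = diag(3),
               translation = rep(0, 3), rmsd = NA_real_,
               nEquivalent = 0L, converged = TRUE, nIterations = 0L)
  rec4 <- identityFromStructuralAlignment(empty, d, b)
  expect_equal(rec4$percent_identity, 0)
  expect_true(rec4$undefined)
})

test_that("global alignment reproduces hand-computed cases", {
  g <- globalAlign("AGW", "AGW")
  expect_equal(g$score, 3)
  expect_equal(g$identity$percent_identity, 100)
  g2 <- globalAlign("AAAA", "AATA")
  expect_equal(g2$score, 2)            # 3 matches - 1 mismatch
  expect_equal(g2$identity$percent_identity, 75)
  expect_equal(g2$alignedA, "AAAA")
  expect_equal(g2$alignedB, "AATA")
  g3 <- globalAlign("ACGT", "AGT")
  expect_equal(g3$score, 1)            # 3 matches - 1 gap
  expect_equal(nchar(g3$alignedA), nchar(g3$alignedB))
  expect_error(globalAlign("", "A"), "non-empty")
})

test_that("global alignment score matches exhaustive enumeration", {
  set.seed(3)
  aa <- strsplit("ACDEFG", "")[[1]]
  for (rep in 1:10) {
    sa <- paste(sample(aa, sample(3:8, 1), TRUE), collapse = "")
    sb <- paste(sample(aa, sample(3:8, 1), TRUE), collapse = "")
    expect_equal(globalAlign(sa, sb)$score, bruteAlignScore(sa, sb))
  }
})

test_that("global alignment score matches the reference implementation", {
  set.seed(4)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sub <- matrix(-1, 20, 20, dimnames = list(aa, aa)); diag(sub) <- 1
  for (rep in 1:5) {
    sa <- paste(sample(aa, 30, TRUE), collapse = "")
    sb <- paste(sample(aa, 30, TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                         substitutionMatrix = sub,
                                         gapOpening = 0, gapExtension = 2)
    expect_equal(globalAlign(sa, sb)$score, Biostrings::score(ref))
    # swap invariance
    expect_equal(globalAlign(sb, sa)$score, globalAlign(sa, sb)$score)
  }
})

test_that("identity histogram bins, fractions and cumulative are coherent", {
  h <- identityHistogram(c(100, 100, 100))
  expect_equal(h$fraction[h$bin_low == 90], 1)
  h2 <- identityHistogram(c(5, 15, 25))
  expect_equal(h2$count[1:3], c(1L, 1L, 1L))
  set.seed(5)
  pid <- runif(200, 0, 100)
  h3 <- identityHistogram(pid)
  expect_equal(sum(h3$fraction), 1)
  expect_equal(h3$cum_fraction[10], 1)
  expect_equal(fractionBelowIdentity(pid, 20), mean(pid < 20))
  expect_equal(sum(h3$count), 200L)
  expect_error(identityHistogram(numeric(0)), "no identity")
})

test_that("percent-identity distances feed tree building", {
  recs <- data.frame(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                     percent_identity = c(100, 25, 25))
  dm <- identityDistanceMatrix(recs)
  v <- as.matrix(dm)
  expect_equal(v["a", "b"], 0)
  expect_equal(v["a", "c"], 75)
  tr <- neighborJoiningTree(dm)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
})
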