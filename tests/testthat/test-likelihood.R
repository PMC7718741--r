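test_that("zero-length branches reduce the likelihood to the root prior", {
  tree <- ape::read.tree(text = "(A:0,B:0);")
  aln <- CodonAlignment("g", c(A = "ATGAAACCC", B = "ATGAAACCC"))
  ll <- codonLogLik(aln, tree, siteClassMix("M0", omega = 0.5),
    kappa = 2, pi = "uniform"
  )
  expect_equal(ll, 3 * log(1 / 61), tolerance = 1e-12)
})

test_that("engine likelihood equals exhaustive marginalization (spot check)", {
  set.seed(202)
  tree <- ape::rtree(4, rooted = FALSE)
  tree$edge.length <- runif(5, 0.05, 0.7)
  mix <- siteClassMix("M2a", p0 = 0.5, p1 = 0.3, omega0 = 0.2, omega2 = 3)
  pi <- rgamma(61, 1)
  pi <- pi / sum(pi)
  aln <- simulateCodonAlignment(tree, mix, kappa = 2.4, nSites = 6, seed = 31)
  eng <- codonLogLik(aln, tree, mix, kappa = 2.4, pi = pi)
  tipStates <- matrix(
    match(codonMatrix(aln)[tree$tip.label, ], oracle_sense_codons()),
    nrow = 4
  )
  ora <- oracle_loglik_4taxa(tree, tipStates, mix, kappa = 2.4, pi = pi)
  expect_equal(eng, ora, tolerance = 1e-8)
})

test_that("missing codons act as fully unobserved tips", {
  tree <- ape::read.tree(text = "((A:0.2,B:0.2):0.1,C:0.3);")
  aln <- CodonAlignment("g", c(A = "ATGAAA", B = "ATG---", C = "ATGNNN"))
  mix <- siteClassMix("M0", omega = 0.4)
  ll <- codonLogLik(aln, tree, mix, kappa = 2, pi = "uniform")
  # second site: B and C unobserved, so it contributes the marginal of A's
  # codon under stationarity, log(1/61)
  aln1 <- CodonAlignment("g", c(A = "ATG", B = "ATG", C = "ATG"))
  tree1 <- tree
  ll1 <- codonLogLik(aln1, tree1, mix, kappa = 2, pi = "uniform")
  expect_equal(ll, ll1 + log(1 / 61), tolerance = 1e-10)
})

test_that("degenerate mixtures collapse to their single live class", {
  tree <- study_tree()
  aln <- simulateCodonAlignment(tree, siteClassMix("M0", omega = 0.3),
    kappa = 2, nSites = 40, seed = 4
  )
  m1 <- siteClassMix("M1a", p0 = 1 - 1e-12, omega0 = 0.3)
  m0 <- siteClassMix("M0", omega = 0.3)
  # proportions (1, 0) make the mixture equal the pure class likelihood;
  # the shared-scale convention weights classes by proportion, so the
  # degenerate mixture has the same per-branch scale as the single class
  expect_equal(
    codonLogLik(aln, tree, m1, kappa = 2, pi = "uniform"),
    codonLogLik(aln, tree, m0, kappa = 2, pi = "uniform"),
    tolerance = 1e-6
  )
})

test_that("unmarked reversible likelihood is invariant to rerooting", {
  tree <- study_tree()
  aln <- simulateCodonAlignment(tree, siteClassMix("M0", omega = 0.3),
    kappa = 2, nSites = 30, seed = 9
  )
  mix <- siteClassMix("M0", omega = 0.44)
  ll <- codonLogLik(aln, tree, mix, kappa = 1.8, pi = "uniform")
  for (og in c("B1", "B4", "F1")) {
    rr <- ape::root(tree, outgroup = og, resolve.root = TRUE)
    expect_equal(
      codonLogLik(aln, rr, mix, kappa = 1.8, pi = "uniform"),
      ll,
      tolerance = 1e-8
    )
  }
})

test_that("compiled and reference pruning implementations agree", {
  tree <- study_tree()
  labels <- study_labels(tree)
  mtree <- markForeground(tree, labels, 1L)$tree
  mix <- siteClassMix("MA", p0 = 0.55, p1 = 0.25, omega0 = 0.12, omega2 = 4)
  aln <- simulateCodonAlignment(mtree, mix, kappa = 2, nSites = 60, seed = 21)
  ctx <- selwide:::.lik_context(aln, mtree)
  pi <- codonFrequencies(aln)
  bl <- ctx$tree$edge.length
  a <- selwide:::.class_loglik(ctx, mix, 2, pi, bl)
  b <- selwide:::.class_loglik_r(ctx, mix, 2, pi, bl)
  expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)
})
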