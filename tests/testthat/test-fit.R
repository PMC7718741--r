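test_that("M0 fitting recovers the generating omega and kappa", {
  tree <- study_tree()
  aln <- simulateCodonAlignment(tree, siteClassMix("M0", omega = 0.3),
    kappa = 2, nSites = 500, seed = 11
  )
  fit <- fitCodonModel(aln, tree, "M0", nStarts = 1, seed = 1)
  w <- siteClasses(fit)$omegaBg[1]
  expect_gt(w, 0.2)
  expect_lt(w, 0.4)
  expect_gt(fit@kappa, 1.5)
  expect_lt(fit@kappa, 2.6)
  expect_identical(fit@convergence, 0L)
})

test_that("model A null pins omega2 at 1 and nests inside model A", {
  tree <- study_tree()
  mtree <- markForeground(tree, study_labels(tree), 1L)$tree
  aln <- simulateCodonAlignment(
    mtree, siteClassMix("MA", p0 = 0.5, p1 = 0.3, omega0 = 0.1, omega2 = 5),
    kappa = 2, nSites = 150, seed = 3
  )
  fn <- fitCodonModel(aln, mtree, "MA_null", nStarts = 1, seed = 1)
  expect_true(all(fn@classes$omegaFg[3:4] == 1))
  fa <- fitCodonModel(aln, fn@tree, "MA",
    nStarts = 1, seed = 2,
    start = list(kappa = fn@kappa)
  )
  expect_gte(fitLnL(fa), fitLnL(fn) - 1e-4)
  # the class table keeps the model A proportion constraints
  cl <- siteClasses(fa)
  expect_equal(sum(cl$prop), 1, tolerance = 1e-9)
  p2 <- 1 - cl$prop[1] - cl$prop[2]
  expect_equal(cl$prop[3], p2 * cl$prop[1] / (cl$prop[1] + cl$prop[2]),
    tolerance = 1e-9
  )
})

test_that("site posteriors are normalized and rank true positive sites higher", {
  tree <- study_tree()
  mtree <- markForeground(tree, study_labels(tree), 1L)$tree
  mix <- siteClassMix("MA", p0 = 0.4, p1 = 0.4, omega0 = 0.1, omega2 = 5)
  aln <- simulateCodonAlignment(mtree, mix, kappa = 2, nSites = 300, seed = 17)
  fit <- fitCodonModel(aln, mtree, "MA", nStarts = 1, seed = 5)
  post <- sitePosteriors(fit, aln)
  expect_equal(unname(rowSums(post)), rep(1, nCodonSites(aln)), tolerance = 1e-9)
  mass <- attr(post, "positive")
  truth <- attr(aln, "siteClass")
  sel <- truth %in% c("2a", "2b")
  expect_gt(mean(mass[sel]), mean(mass[!sel]))
})

test_that("site posteriors refuse branch models and honor zero weights", {
  tree <- study_tree()
  aln <- simulateCodonAlignment(tree, siteClassMix("M0", omega = 0.3),
    kappa = 2, nSites = 50, seed = 2
  )
  fit <- fitCodonModel(aln, tree, "M0", nStarts = 1, seed = 1)
  expect_error(sitePosteriors(fit, aln), "site")

  # a hand-built M2a fit with zero weight on the positive class
  m <- fitCodonModel(aln, tree, "M1a", nStarts = 1, seed = 1)
  fake <- new("CodonFit",
    modelId = "M2a", lnL = fitLnL(m), kappa = m@kappa, pi = m@pi,
    classes = data.frame(
      class = c("0", "1", "2"),
      prop = c(m@classes$prop, 0),
      omegaBg = c(m@classes$omegaBg, 2),
      omegaFg = c(m@classes$omegaFg, 2)
    ),
    tree = m@tree, convergence = 0L, boundary = character(), nStarts = 1L
  )
  post <- sitePosteriors(fake, aln)
  expect_true(all(attr(post, "positive") == 0))
})

test_that("fixed branch lengths are honored", {
  tree <- study_tree()
  aln <- simulateCodonAlignment(tree, siteClassMix("M0", omega = 0.3),
    kappa = 2, nSites = 120, seed = 8
  )
  fit <- fitCodonModel(aln, tree, "M0", nStarts = 1, seed = 1, fixBranchLengths = TRUE)
  ord <- stats::reorder(tree, "postorder")
  expect_equal(fit@tree$edge.length, ord$edge.length, tolerance = 1e-12)
})
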