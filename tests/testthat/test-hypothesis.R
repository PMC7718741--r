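test_that("LRT statistic and chi-square tail match the integration oracle", {
  # frozen values computed by numerical integration of the chi-square
  # density: P(chi2_1 > 6) and P(chi2_2 > 5)
  r <- lrTest(-100, -97, df = 1)
  expect_equal(r$statistic, 6)
  expect_equal(r$pValue, 0.01430587844, tolerance = 1e-9)
  r2 <- lrTest(-10, -7.5, df = 2)
  expect_equal(r2$statistic, 5)
  expect_equal(r2$pValue, 0.08208499862, tolerance = 1e-9)
})

test_that("LRT clamps optimizer jitter and is monotone in the statistic", {
  same <- lrTest(-50, -50, df = 1)
  expect_identical(same$statistic, 0)
  expect_identical(same$pValue, 1)
  jitter <- lrTest(-50, -50.001, df = 1)
  expect_identical(jitter$statistic, 0)
  expect_identical(jitter$pValue, 1)
  stats <- seq(0, 10, by = 0.5)
  ps <- vapply(stats, function(s) lrTest(0, s / 2, 1)$pValue, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("Bonferroni correction divides the level by the test count", {
  expect_equal(bonferroniAlpha(0.05, 1), 0.05)
  expect_equal(bonferroniAlpha(0.05, 2), 0.025)
  expect_equal(bonferroniAlpha(0.05, 4), 0.0125)
  # doubling the test count halves the level exactly
  for (n in c(1, 3, 7)) {
    expect_identical(bonferroniAlpha(0.05, 2 * n), bonferroniAlpha(0.05, n) / 2)
  }
  expect_error(bonferroniAlpha(0.05, 0))
})

# minimal CodonFit stand-ins for classification rules
fakeFit <- function(modelId, lnL, omegaFg = 1, omegaBg = 0.3) {
  cl <- switch(modelId,
    M0 = siteClassMix("M0", omega = omegaBg),
    two_ratios = siteClassMix("two_ratios", omega = omegaBg, omegaFg = omegaFg),
    MA_null = siteClassMix("MA_null", p0 = 0.5, p1 = 0.3, omega0 = omegaBg),
    MA = siteClassMix("MA", p0 = 0.5, p1 = 0.3, omega0 = omegaBg, omega2 = max(omegaFg, 1))
  )
  new("CodonFit",
    modelId = modelId, lnL = lnL, kappa = 2, pi = rep(1 / 61, 61),
    classes = cl, tree = NULL, convergence = 0L, boundary = character(),
    nStarts = 1L
  )
}

test_that("branch candidates need both significance and foreground omega > 1", {
  aln <- CodonAlignment("g", c(A = "ATGAAA", B = "ATGAAG"))
  # p ~ 0.0016 (stat 10), omega_fg 2.3: candidate
  o <- classifyOutcome(
    "g", 1L, fakeFit("M0", -105), fakeFit("two_ratios", -100, omegaFg = 2.3),
    aln
  )
  expect_true(isCandidate(o))
  # same significance, omega_fg 0.8: not a candidate
  o2 <- classifyOutcome(
    "g", 1L, fakeFit("M0", -105), fakeFit("two_ratios", -100, omegaFg = 0.8),
    aln
  )
  expect_false(isCandidate(o2))
  # not significant, omega_fg large: not a candidate
  o3 <- classifyOutcome(
    "g", 1L, fakeFit("M0", -100.5), fakeFit("two_ratios", -100, omegaFg = 9),
    aln
  )
  expect_false(isCandidate(o3))
  expect_identical(o3@df, 1L)
})

test_that("sites are only reported when the LRT is significant", {
  aln <- CodonAlignment("g", c(A = "ATGAAA", B = "ATGAAG"))
  # external site table stands in for posteriors above threshold
  beb <- data.frame(site = c(3, 9), posterior = c(0.95, 0.99))
  sig <- classifyOutcome(
    "g", 1L, fakeFit("MA_null", -110), fakeFit("MA", -100, omegaFg = 4),
    aln,
    sites = beb
  )
  expect_identical(sig@positiveSites$site, c(3L, 9L))
  insig <- classifyOutcome(
    "g", 1L, fakeFit("MA_null", -100.1), fakeFit("MA", -100, omegaFg = 4),
    aln,
    sites = beb
  )
  expect_identical(nrow(insig@positiveSites), 0L)
  # threshold is strict: a posterior exactly at 0.9 is excluded
  sig2 <- classifyOutcome(
    "g", 1L, fakeFit("MA_null", -110), fakeFit("MA", -100, omegaFg = 4),
    aln,
    sites = data.frame(site = c(1, 2), posterior = c(0.9, 0.91))
  )
  expect_identical(sig2@positiveSites$site, 2L)
})

test_that("alpha bookkeeping flows into the candidate call", {
  aln <- CodonAlignment("g", c(A = "ATGAAA", B = "ATGAAG"))
  # stat 6 -> p ~ 0.0143: significant at 0.05, not at 0.0125 (4 clades)
  oc <- classifyOutcome(
    "g", 1L, fakeFit("M0", -103), fakeFit("two_ratios", -100, omegaFg = 2),
    aln,
    alphaUsed = bonferroniAlpha(0.05, 4)
  )
  expect_false(isCandidate(oc))
  expect_equal(oc@alphaUsed, 0.0125)
})
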