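# Likelihood-ratio tests, Bonferroni correction and candidate calls.

.MODEL_PAIRS <- list(
  branch = list(null = "M0", alt = "two_ratios", df = 1L),
  site = list(null = "M1a", alt = "M2a", df = 2L),
  `branch-site` = list(null = "MA_null", alt = "MA", df = 1L)
)

#' Likelihood-ratio test between nested codon models
#'
#' The statistic is `max(0, 2 * (lnLAlt - lnLNull))` (optimizer jitter can
#' make the difference marginally negative; it is clamped) and the p-value
#' is the upper tail of the chi-square distribution with `df` degrees of
#' freedom. Degrees of freedom for the built-in pairs: M0 vs two-ratios 1,
#' M1a vs M2a 2, model A null vs model A 1.
#'
#' @param lnLNull,lnLAlt Maximized log-likelihoods.
#' @param df Degrees of freedom (1 or 2 for the built-in pairs).
#' @return List with `statistic` and `pValue`.
#' @export
#' @examples
#' lrTest(-100, -97, df = 1) # statistic 6, p ~ 0.0143
lrTest <- function(lnLNull, lnLAlt, df) {
  stopifnot(is.finite(lnLNull), is.finite(lnLAlt), df >= 1)
  stat <- max(0, 2 * (lnLAlt - lnLNull))
  list(statistic = stat, pValue = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Bonferroni-corrected significance level
#'
#' `alpha / nTests`, for use when several foreground clades are tested in
#' one run.
#'
#' @param alpha Nominal level in (0, 1).
#' @param nTests Number of tested hypotheses (foreground clades), >= 1.
#' @return Corrected level.
#' @export
#' @examples
#' bonferroniAlpha(0.05, 2) # 0.025
bonferroniAlpha <- function(alpha, nTests) {
  stopifnot(alpha > 0, alpha < 1)
  if (nTests < 1) stop("nTests must be >= 1")
  alpha / nTests
}

#' Classify a tested gene as a positive-selection candidate
#'
#' A gene is a candidate iff its LRT p-value is below the (possibly
#' Bonferroni-corrected) level and, for branch and branch-site models, the
#' foreground omega of the alternative fit exceeds one. Positively
#' selected codon positions are reported for site and branch-site models
#' only when the LRT is significant: 1-based alignment positions whose
#' positive-class posterior exceeds `siteThreshold`.
#'
#' @param geneId,cladeId Identifiers for the outcome.
#' @param fitNull,fitAlt [CodonFit-class] objects for the two hypotheses.
#' @param aln The alignment (needed for site posteriors).
#' @param alphaUsed Significance level after any correction (default 0.05).
#' @param siteThreshold Posterior threshold for reporting sites (default
#'   0.9).
#' @param sites Optional externally computed site table (`site`,
#'   `posterior`), e.g. parsed BEB output; used in place of the internal
#'   NEB posteriors, still only when the LRT is significant.
#' @return A [SelectionTest-class].
#' @export
classifyOutcome <- function(geneId, cladeId, fitNull, fitAlt, aln,
                            alphaUsed = 0.05, siteThreshold = 0.9,
                            sites = NULL) {
  pairName <- paste0(fitNull@modelId, "_vs_", fitAlt@modelId)
  df <- switch(pairName,
    M0_vs_two_ratios = 1L,
    M1a_vs_M2a = 2L,
    MA_null_vs_MA = 1L,
    stop("unsupported model pair: ", pairName)
  )
  lr <- lrTest(fitNull@lnL, fitAlt@lnL, df)
  branchLike <- fitAlt@modelId %in% c("two_ratios", "MA")
  omegaFg <- if (branchLike) omegaForeground(fitAlt) else NA_real_
  omegaBg <- if (fitAlt@modelId == "two_ratios") {
    omegaBackground(fitAlt)
  } else if (fitAlt@modelId %in% c("MA", "M2a")) {
    omegaBackground(fitAlt)
  } else {
    NA_real_
  }
  significant <- lr$pValue < alphaUsed
  candidate <- significant && (!branchLike || omegaFg > 1)
  siteTab <- data.frame(site = integer(), posterior = numeric())
  if (significant && fitAlt@modelId %in% c("M2a", "MA")) {
    if (!is.null(sites)) {
      keep <- sites$posterior > siteThreshold
      siteTab <- data.frame(
        site = as.integer(sites$site[keep]),
        posterior = sites$posterior[keep]
      )
    } else {
      post <- sitePosteriors(fitAlt, aln)
      mass <- attr(post, "positive")
      hit <- which(mass > siteThreshold)
      siteTab <- data.frame(site = hit, posterior = mass[hit])
    }
  }
  new("SelectionTest",
    geneId = as.character(geneId), cladeId = as.integer(cladeId),
    modelPair = pairName, lnLNull = fitNull@lnL, lnLAlt = fitAlt@lnL,
    statistic = lr$statistic, df = df, pValue = lr$pValue,
    alphaUsed = alphaUsed, candidate = candidate,
    omegaFg = omegaFg, omegaBg = omegaBg, positiveSites = siteTab
  )
}
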