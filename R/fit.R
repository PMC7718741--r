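# Maximum-likelihood fitting of the nested codon models.
#
# All free parameters are optimized on transformed scales (log kappa, log
# omega, stick-breaking logits for mixture proportions, log branch lengths)
# with box constraints, by L-BFGS-B. Multi-start initial points are drawn
# from a seeded generator so fits are reproducible.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.logit <- function(p) log(p / (1 - p))

.OMEGA_MIN <- 1e-4
.OMEGA_MAX <- 999
.OMEGA0_MAX <- 0.9999
.KAPPA_BOX <- log(c(1e-2, 100))
.BL_BOX <- log(c(1e-8, 50))
.LOGIT_BOX <- c(-12, 12)

# Parameter packing: returns list(init, lower, upper, unpack) where
# unpack(theta) -> list(kappa, mix, bl)
.model_param_spec <- function(model, nbl, bl0, start = list()) {
  g <- function(nm, d) if (!is.null(start[[nm]])) start[[nm]] else d
  kap <- log(g("kappa", 2))
  blv <- log(pmax(bl0, 1e-4))
  core <- switch(model,
    M0 = list(
      init = c(kap, log(g("omega", 0.3))),
      lower = c(.KAPPA_BOX[1], log(.OMEGA_MIN)),
      upper = c(.KAPPA_BOX[2], log(.OMEGA_MAX)),
      mix = function(th) siteClassMix("M0", omega = exp(th[2]))
    ),
    two_ratios = list(
      init = c(kap, log(g("omega", 0.3)), log(g("omegaFg", 0.5))),
      lower = c(.KAPPA_BOX[1], log(.OMEGA_MIN), log(.OMEGA_MIN)),
      upper = c(.KAPPA_BOX[2], log(.OMEGA_MAX), log(.OMEGA_MAX)),
      mix = function(th) {
        siteClassMix("two_ratios", omega = exp(th[2]), omegaFg = exp(th[3]))
      }
    ),
    M1a = list(
      init = c(kap, .logit(g("p0", 0.7)), log(g("omega0", 0.1))),
      lower = c(.KAPPA_BOX[1], .LOGIT_BOX[1], log(.OMEGA_MIN)),
      upper = c(.KAPPA_BOX[2], .LOGIT_BOX[2], log(.OMEGA0_MAX)),
      mix = function(th) {
        siteClassMix("M1a", p0 = .sigmoid(th[2]), omega0 = exp(th[3]))
      }
    ),
    M2a = list(
      init = c(
        kap, .logit(g("s1", 0.65)), .logit(g("s2", 0.7)),
        log(g("omega0", 0.1)), log(g("omega2", 2) - 1 + 1e-6)
      ),
      lower = c(.KAPPA_BOX[1], .LOGIT_BOX[1], .LOGIT_BOX[1], log(.OMEGA_MIN), log(1e-6)),
      upper = c(.KAPPA_BOX[2], .LOGIT_BOX[2], .LOGIT_BOX[2], log(.OMEGA0_MAX), log(.OMEGA_MAX - 1)),
      mix = function(th) {
        p0 <- .sigmoid(th[2])
        p1 <- (1 - p0) * .sigmoid(th[3])
        siteClassMix("M2a",
          p0 = p0, p1 = p1,
          omega0 = exp(th[4]), omega2 = max(1, 1 + exp(th[5]) - 1e-6)
        )
      }
    ),
    MA = list(
      init = c(
        kap, .logit(g("s1", 0.65)), .logit(g("s2", 0.7)),
        log(g("omega0", 0.1)), log(g("omega2", 2) - 1 + 1e-6)
      ),
      lower = c(.KAPPA_BOX[1], .LOGIT_BOX[1], .LOGIT_BOX[1], log(.OMEGA_MIN), log(1e-6)),
      upper = c(.KAPPA_BOX[2], .LOGIT_BOX[2], .LOGIT_BOX[2], log(.OMEGA0_MAX), log(.OMEGA_MAX - 1)),
      mix = function(th) {
        p0 <- .sigmoid(th[2])
        p1 <- (1 - p0) * .sigmoid(th[3])
        siteClassMix("MA",
          p0 = p0, p1 = p1,
          omega0 = exp(th[4]), omega2 = max(1, 1 + exp(th[5]) - 1e-6)
        )
      }
    ),
    MA_null = list(
      init = c(kap, .logit(g("s1", 0.65)), .logit(g("s2", 0.7)), log(g("omega0", 0.1))),
      lower = c(.KAPPA_BOX[1], .LOGIT_BOX[1], .LOGIT_BOX[1], log(.OMEGA_MIN)),
      upper = c(.KAPPA_BOX[2], .LOGIT_BOX[2], .LOGIT_BOX[2], log(.OMEGA0_MAX)),
      mix = function(th) {
        p0 <- .sigmoid(th[2])
        p1 <- (1 - p0) * .sigmoid(th[3])
        siteClassMix("MA_null", p0 = p0, p1 = p1, omega0 = exp(th[4]))
      }
    ),
    stop("unknown model: ", model)
  )
  ncore <- length(core$init)
  list(
    init = c(core$init, blv),
    lower = c(core$lower, rep(.BL_BOX[1], nbl)),
    upper = c(core$upper, rep(.BL_BOX[2], nbl)),
    ncore = ncore,
    unpack = function(th) {
      list(
        kappa = exp(th[1]),
        mix = core$mix(th),
        bl = exp(th[ncore + seq_len(nbl)])
      )
    }
  )
}

#' Fit a codon model by maximum likelihood
#'
#' Maximizes the mixture log-likelihood of [codonLogLik()] over kappa, the
#' model's free omega/proportion parameters, and (by default) all branch
#' lengths, under the constraints of [siteClassMix()]. Optimization is
#' bounded quasi-Newton (L-BFGS-B) on transformed parameters with
#' `nStarts` seeded starting points; the best run is returned.
#'
#' @param aln A [CodonAlignment-class].
#' @param tree `ape::phylo`, marked by [markForeground()] for branch and
#'   branch-site models. Existing branch lengths seed the optimizer; if
#'   absent, all branches start at 0.1.
#' @param model One of `"M0"`, `"two_ratios"`, `"M1a"`, `"M2a"`,
#'   `"MA_null"`, `"MA"`.
#' @param pi Codon frequencies: `"F3x4"` (default), `"uniform"`, or a
#'   61-vector.
#' @param nStarts Number of optimizer starts (first is a deterministic
#'   heuristic, the rest are seeded jitters of it).
#' @param seed Integer seed for the start-point generator.
#' @param fixBranchLengths If `TRUE`, branch lengths are held at the values
#'   on `tree` (which must then have them) and only substitution
#'   parameters are optimized — the usual speed-up of reusing lengths from
#'   a one-ratio fit.
#' @param start Optional named list of starting values
#'   (`kappa`, `omega`, `omega0`, `omega2`, ...) overriding the heuristic.
#' @param control Passed to [stats::optim()]'s control (defaults:
#'   `maxit = 500`, `factr = 1e7`).
#' @return A [CodonFit-class] object.
#' @export
fitCodonModel <- function(aln, tree, model = .MODEL_IDS, pi = "F3x4",
                          nStarts = 3L, seed = 1L, fixBranchLengths = FALSE,
                          start = list(), control = list()) {
  model <- match.arg(model)
  if (is.character(pi)) pi <- codonFrequencies(aln, pi)
  ctx <- .lik_context(aln, tree)
  nedge <- nrow(ctx$edge)
  bl_fixed <- NULL
  if (fixBranchLengths) {
    if (is.null(ctx$tree$edge.length)) stop("fixBranchLengths requires branch lengths on the tree")
    bl_fixed <- ctx$tree$edge.length
    nbl <- 0L
  } else {
    nbl <- nedge
  }
  bl0 <- if (!is.null(ctx$tree$edge.length)) pmax(ctx$tree$edge.length, 1e-4) else rep(0.1, nedge)
  spec <- .model_param_spec(model, nbl, bl0, start)
  ctrl <- utils::modifyList(list(maxit = 500, factr = 1e7), control)

  negll <- function(th) {
    # the whole evaluation sits inside try(): finite-difference probes can
    # step marginally outside the box and must score badly, not abort
    v <- try(
      {
        p <- spec$unpack(th)
        bl <- if (fixBranchLengths) bl_fixed else p$bl
        .mix_loglik(ctx, p$mix, p$kappa, pi, bl)
      },
      silent = TRUE
    )
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else -v
  }

  set.seed(as.integer(seed %% .Machine$integer.max))
  best <- NULL
  for (s in seq_len(max(1L, nStarts))) {
    init <- spec$init
    if (s > 1L) {
      init <- init + stats::rnorm(length(init), 0, 0.5)
      init <- pmin(pmax(init, spec$lower), spec$upper)
    }
    fit <- try(
      stats::optim(init, negll,
        method = "L-BFGS-B",
        lower = spec$lower, upper = spec$upper, control = ctrl
      ),
      silent = TRUE
    )
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10) {
    stop("codon model optimization failed to converge for gene ", geneId(aln))
  }
  p <- spec$unpack(best$par)
  tr <- ctx$tree
  tr$edge.length <- if (fixBranchLengths) bl_fixed else p$bl

  boundary <- character()
  mx <- p$mix
  if (model %in% c("M2a", "MA")) {
    w2 <- max(mx$omegaFg)
    if (w2 - 1 < 1e-3) boundary <- c(boundary, "omega2")
    p2 <- 1 - mx$prop[1] - mx$prop[2]
    if (p2 < 1e-4) boundary <- c(boundary, "p2")
  }
  if (model %in% c("M1a", "M2a", "MA", "MA_null") && mx$omegaBg[1] >= .OMEGA0_MAX - 1e-6) {
    boundary <- c(boundary, "omega0")
  }

  new("CodonFit",
    modelId = model, lnL = -best$value, kappa = p$kappa, pi = pi,
    classes = mx, tree = tr, convergence = as.integer(best$convergence),
    boundary = boundary, nStarts = as.integer(nStarts)
  )
}

#' Per-site class posteriors (naive empirical Bayes)
#'
#' Computes \eqn{P(\mathrm{class}\ k \mid \mathrm{site}) \propto \hat p_k
#' L(\mathrm{site} \mid k)} at the fitted parameter values — the NEB
#' calculation. The positive-selection mass at a site is the posterior of
#' the classes whose foreground omega is free to exceed one: class 2 of
#' M2a, classes 2a + 2b of model A. For M1a no such class exists and the
#' positive mass is zero everywhere.
#'
#' @param fit A [CodonFit-class] for a site or branch-site model (M1a,
#'   M2a, MA_null, MA); branch models have no site classes and raise an
#'   error.
#' @param aln The alignment the model was fitted to.
#' @return Matrix (sites x classes) of posterior probabilities, with an
#'   attribute `"positive"` giving the per-site positive-class mass.
#' @export
sitePosteriors <- function(fit, aln) {
  if (!fit@modelId %in% c("M1a", "M2a", "MA_null", "MA")) {
    stop("site posteriors are defined only for site and branch-site models")
  }
  res <- codonLogLik(aln, fit@tree, fit@classes, fit@kappa, fit@pi, perSite = TRUE)
  lw <- sweep(res$classLogLik, 2, log(fit@classes$prop), "+")
  m <- apply(lw, 1, max)
  post <- exp(lw - m)
  post <- post / rowSums(post)
  colnames(post) <- fit@classes$class
  posClasses <- switch(fit@modelId,
    M2a = "2",
    MA = ,
    MA_null = c("2a", "2b"),
    M1a = character()
  )
  posMass <- if (length(posClasses)) {
    rowSums(post[, posClasses, drop = FALSE])
  } else {
    rep(0, nrow(post))
  }
  # classes with zero fitted weight carry zero posterior by definition
  zero <- fit@classes$prop <= 0
  if (any(zero)) post[, zero] <- 0
  attr(post, "positive") <- posMass
  post
}
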