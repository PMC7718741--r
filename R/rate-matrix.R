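#' Goldman-Yang codon instantaneous rate matrix
#'
#' Builds the 61 x 61 GY94-style rate matrix. Codons differing at more than
#' one nucleotide position exchange at rate 0; a single-position change from
#' codon i to codon j has rate \eqn{\pi_j}, multiplied by \eqn{\kappa} if the
#' change is a transition and by \eqn{\omega} if it is nonsynonymous. The
#' diagonal makes rows sum to zero and the matrix is rescaled so that the
#' expected number of substitutions per codon per unit time is one:
#' \eqn{-\sum_i \pi_i q_{ii} = 1}.
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega Nonsynonymous/synonymous rate ratio (dN/dS), >= 0.
#' @param pi Equilibrium frequencies over the 61 sense codons, in
#'   [senseCodons()] order; must be nonnegative and sum to 1.
#' @return 61 x 61 numeric matrix with row/column names the sense codons.
#' @export
#' @examples
#' Q <- codonRateMatrix(kappa = 2, omega = 0.3, pi = rep(1 / 61, 61))
#' range(rowSums(Q)) # ~ 0
codonRateMatrix <- function(kappa, omega, pi) {
  stopifnot(length(kappa) == 1L, kappa > 0, length(omega) == 1L, omega >= 0)
  if (length(pi) != 61L || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be 61 nonnegative frequencies summing to 1")
  }
  tb <- .CODON_TABLES
  Q <- matrix(0, 61, 61, dimnames = list(.SENSE_CODONS, .SENSE_CODONS))
  Q[tb$NEIGHBOR] <- rep(pi, each = 61)[tb$NEIGHBOR]
  Q[tb$TS] <- Q[tb$TS] * kappa
  Q[tb$NEIGHBOR & tb$NONSYN] <- Q[tb$NEIGHBOR & tb$NONSYN] * omega
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale > 0) Q <- Q / scale
  Q
}

# Unscaled GY rate matrix (no mean-rate normalization).
.codon_qraw <- function(kappa, omega, pi) {
  tb <- .CODON_TABLES
  Q <- matrix(0, 61, 61)
  Q[tb$NEIGHBOR] <- rep(pi, each = 61)[tb$NEIGHBOR]
  Q[tb$TS] <- Q[tb$TS] * kappa
  Q[tb$NEIGHBOR & tb$NONSYN] <- Q[tb$NEIGHBOR & tb$NONSYN] * omega
  diag(Q) <- -rowSums(Q)
  Q
}

# Mean substitution flux of the unscaled matrix, split into synonymous and
# nonsynonymous parts: the mean rate at a given omega is syn + nonsyn*omega.
.gy_flux <- function(kappa, pi) {
  tb <- .CODON_TABLES
  R <- matrix(0, 61, 61)
  R[tb$NEIGHBOR] <- rep(pi, each = 61)[tb$NEIGHBOR]
  R[tb$TS] <- R[tb$TS] * kappa
  R <- R * pi # pi_i * rate_ij
  ns <- tb$NEIGHBOR & tb$NONSYN
  c(syn = sum(R[tb$NEIGHBOR & !tb$NONSYN]), nonsyn = sum(R[ns]))
}

# Common per-branch-type scale for a site-class mixture: branch lengths
# count expected substitutions per codon averaged over site classes, so
# every class shares one scale and the synonymous rate is constant across
# classes (the codeml convention). For a single class this reduces to the
# matrix's own mean rate.
.mix_scales <- function(mix, kappa, pi) {
  fl <- .gy_flux(kappa, pi)
  c(
    bg = fl[["syn"]] + fl[["nonsyn"]] * sum(mix$prop * mix$omegaBg),
    fg = fl[["syn"]] + fl[["nonsyn"]] * sum(mix$prop * mix$omegaFg)
  )
}

# Cache of eigendecompositions across likelihood evaluations: during
# finite-difference gradients most evaluations leave (kappa, omega)
# untouched, so the decompositions are reusable.
.EIGEN_CACHE <- new.env(parent = emptyenv())

# Eigendecomposition of the reversible Q via the pi^{1/2} similarity
# transform. Returns objects from which P(t) = U %*% (exp(lambda t) * W)
# is assembled with two dense products. `scaled` selects the mean-rate-1
# normalized matrix (single-model use) or the raw matrix (mixture use,
# where the caller divides branch lengths by a shared scale).
.codon_eigen <- function(kappa, omega, pi, scaled = TRUE) {
  key <- sprintf(
    "%.17g_%.17g_%d_%.17g", kappa, omega, scaled,
    sum(pi * seq_len(61))
  )
  hit <- .EIGEN_CACHE[[key]]
  if (!is.null(hit)) return(hit)
  d <- .codon_eigen_compute(kappa, omega, pi, scaled)
  if (length(ls(.EIGEN_CACHE)) > 400) {
    rm(list = ls(.EIGEN_CACHE), envir = .EIGEN_CACHE)
  }
  assign(key, d, envir = .EIGEN_CACHE)
  d
}

.codon_eigen_compute <- function(kappa, omega, pi, scaled = TRUE) {
  Q <- if (scaled) codonRateMatrix(kappa, omega, pi) else .codon_qraw(kappa, omega, pi)
  sp <- sqrt(pi)
  # guard zero frequencies (floored upstream, but be safe)
  sp[sp == 0] <- 1e-12
  S <- Q * (sp %o% (1 / sp))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(
    values = e$values,
    U = e$vectors / sp,          # diag(1/sqrt(pi)) %*% V
    W = t(e$vectors * sp)        # t(V) %*% diag(sqrt(pi))
  )
}

# Transition probability matrix P(t) = exp(Qt) from a cached decomposition.
.codon_pmat <- function(dec, t) {
  P <- dec$U %*% (exp(dec$values * t) * dec$W)
  # clip eigen-roundoff; magnitudes are ~1e-15
  P[P < 0] <- 0
  P
}

#' Codon transition probability matrix
#'
#' \eqn{P(t) = \exp(Qt)} for the rate matrix of [codonRateMatrix()],
#' computed by symmetric eigendecomposition (Q is time-reversible).
#'
#' @inheritParams codonRateMatrix
#' @param t Branch length in expected substitutions per codon, >= 0.
#' @return 61 x 61 stochastic matrix.
#' @export
codonTransitionMatrix <- function(kappa, omega, pi, t) {
  stopifnot(t >= 0)
  .codon_pmat(.codon_eigen(kappa, omega, pi), t)
}

#' Equilibrium codon frequencies from an alignment
#'
#' The F3x4 estimator: nucleotide frequencies are tallied separately at the
#' three codon positions over all non-missing codons, each sense codon's
#' frequency is the product of its three positional frequencies, and the
#' 61-vector is renormalized (stop codons absorb no mass). `"uniform"`
#' returns 1/61 everywhere. Frequencies are floored at 1e-8 before
#' renormalization so that codons absent from a short alignment keep a
#' nonzero equilibrium probability.
#'
#' @param x A [CodonAlignment-class] object.
#' @param method `"F3x4"` (default) or `"uniform"`.
#' @return Named numeric vector of length 61 summing to 1.
#' @export
codonFrequencies <- function(x, method = c("F3x4", "uniform")) {
  method <- match.arg(method)
  if (method == "uniform") {
    return(stats::setNames(rep(1 / 61, 61), .SENSE_CODONS))
  }
  cod <- codonMatrix(x)
  cod <- cod[!is.na(.codon_index(cod))]
  if (length(cod) == 0L) stop("alignment has no unambiguous codons")
  nucs <- do.call(rbind, strsplit(cod, ""))
  f <- sapply(1:3, function(p) {
    tab <- table(factor(nucs[, p], levels = .NUC))
    as.numeric(tab) / sum(tab)
  })
  pi <- f[match(.SENSE_NUC[, 1], .NUC), 1] *
    f[match(.SENSE_NUC[, 2], .NUC), 2] *
    f[match(.SENSE_NUC[, 3], .NUC), 3]
  pi <- pmax(pi, 1e-8)
  stats::setNames(pi / sum(pi), .SENSE_CODONS)
}
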