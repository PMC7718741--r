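# Felsenstein pruning over a site-class mixture.
#
# Trees are ape::phylo objects. Foreground branches are identified through
# an optional `node.mark` element: an integer vector indexed by node id
# (tips 1..Ntip, then internals) giving the mark of the edge ABOVE that
# node; 0 or absent means background. Marks keyed by child node survive
# ape's edge reordering, unlike per-edge-row vectors.

.edge_marks <- function(tree) {
  nm <- tree$node.mark
  if (is.null(nm)) return(integer(nrow(tree$edge)))
  out <- nm[tree$edge[, 2]]
  out[is.na(out)] <- 0L
  as.integer(out)
}

# Static context reused across likelihood evaluations during optimization.
.lik_context <- function(aln, tree) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- tree$tip.label
  missing <- setdiff(taxa, alignmentTaxa(aln))
  if (length(missing)) {
    stop("tree tips absent from alignment: ", paste(missing, collapse = ", "))
  }
  tr <- stats::reorder(tree, "postorder")
  idx <- matrix(
    .codon_index(codonMatrix(aln)[taxa, , drop = FALSE]),
    nrow = length(taxa),
    dimnames = list(taxa, NULL)
  )
  key <- apply(idx, 2, paste, collapse = ",")
  keep <- !duplicated(key)
  map <- match(key, key[keep])
  list(
    tree = tr,
    edge = tr$edge,
    marks = .edge_marks(tr),
    ntip = length(taxa),
    nnode = tr$Nnode,
    tips = idx[, keep, drop = FALSE],
    weights = tabulate(map, nbins = sum(keep)),
    map = map,
    npat = sum(keep)
  )
}

# Per-pattern per-class log-likelihoods at given parameter values.
# bl: edge lengths aligned with ctx$edge rows (expected substitutions per
# codon, averaged over site classes). Returns npat x nclass matrix.
# The pruning inner loop runs in C++; .class_loglik_r is the pure-R
# implementation of the same recursion, kept for cross-checking.
.class_loglik <- function(ctx, mix, kappa, pi, bl) {
  omegas <- sort(unique(c(mix$omegaBg, mix$omegaFg)))
  ndec <- length(omegas)
  U <- array(0, c(61, 61, ndec))
  W <- array(0, c(61, 61, ndec))
  lambda <- matrix(0, 61, ndec)
  for (i in seq_len(ndec)) {
    d <- .codon_eigen(kappa, omegas[i], pi, scaled = FALSE)
    U[, , i] <- d$U
    W[, , i] <- d$W
    lambda[, i] <- d$values
  }
  decIdx <- cbind(match(mix$omegaBg, omegas), match(mix$omegaFg, omegas))
  scales <- .mix_scales(mix, kappa, pi)
  tips <- ctx$tips
  tips[is.na(tips)] <- 0L
  storage.mode(tips) <- "integer"
  out <- .cpp_class_loglik(
    tips, ctx$edge, as.integer(ctx$marks), bl,
    U, W, lambda, decIdx, unname(scales), pi
  )
  colnames(out) <- mix$class
  out
}

.class_loglik_r <- function(ctx, mix, kappa, pi, bl) {
  decs <- list()
  pmats <- list()
  # P(t) cached per (omega, scaled time): classes share matrices wherever
  # their omega coincides on a branch type (frequent under M1a/M2a/MA)
  pmat_for <- function(omega, tt) {
    key <- sprintf("%.17g_%.17g", omega, tt)
    P <- pmats[[key]]
    if (is.null(P)) {
      dkey <- sprintf("%.17g", omega)
      d <- decs[[dkey]]
      if (is.null(d)) {
        d <- .codon_eigen(kappa, omega, pi, scaled = FALSE)
        decs[[dkey]] <<- d
      }
      P <- .codon_pmat(d, tt)
      pmats[[key]] <<- P
    }
    P
  }
  scales <- .mix_scales(mix, kappa, pi)
  ntip <- ctx$ntip
  npat <- ctx$npat
  root <- ctx$edge[nrow(ctx$edge), 1]
  nclass <- nrow(mix)
  out <- matrix(NA_real_, npat, nclass)
  for (k in seq_len(nclass)) {
    w_bg <- mix$omegaBg[k]
    w_fg <- mix$omegaFg[k]
    part <- vector("list", ntip + ctx$nnode)
    logscale <- numeric(npat)
    for (e in seq_len(nrow(ctx$edge))) {
      child <- ctx$edge[e, 2]
      parent <- ctx$edge[e, 1]
      fgEdge <- ctx$marks[e] > 0L
      omega <- if (fgEdge) w_fg else w_bg
      rate <- scales[[if (fgEdge) "fg" else "bg"]]
      P <- pmat_for(omega, bl[e] / rate)
      if (child <= ntip) {
        st <- ctx$tips[child, ]
        contrib <- matrix(1, 61, npat)
        ok <- !is.na(st)
        contrib[, ok] <- P[, st[ok]]
      } else {
        cp <- part[[child]]
        sc <- colSums(cp) / 61
        sc[sc <= 0] <- 1
        logscale <- logscale + log(sc)
        contrib <- P %*% (cp / rep(sc, each = 61))
      }
      part[[parent]] <- if (is.null(part[[parent]])) contrib else part[[parent]] * contrib
    }
    out[, k] <- log(colSums(pi * part[[root]])) + logscale
  }
  colnames(out) <- mix$class
  out
}

.mix_loglik <- function(ctx, mix, kappa, pi, bl, perPattern = FALSE) {
  cl <- .class_loglik(ctx, mix, kappa, pi, bl)
  lw <- sweep(cl, 2, log(mix$prop), "+")
  m <- apply(lw, 1, max)
  pat <- m + log(rowSums(exp(lw - m)))
  pat[!is.finite(m)] <- -Inf
  if (perPattern) list(lnL = sum(ctx$weights * pat), pat = pat, classLogLik = cl)
  else sum(ctx$weights * pat)
}

#' Log-likelihood of a codon alignment under a site-class mixture
#'
#' Computes the phylogenetic log-likelihood by Felsenstein pruning:
#' \deqn{\ell = \sum_s \log \sum_k p_k L(s \mid k)} where class k uses its
#' foreground omega on branches marked as foreground (see
#' [markForeground()]) and its background omega elsewhere. Transition
#' probabilities are matrix exponentials of the Goldman-Yang rate matrix;
#' all site classes share one scale per branch type (the mixture-weighted
#' mean rate), so branch lengths count expected substitutions per codon
#' averaged over site classes and the synonymous rate is identical across
#' classes. Codons containing `-` or `N` contribute all-ones partial
#' vectors; the root is weighted by the equilibrium frequencies.
#'
#' @param aln A [CodonAlignment-class]; must contain every tree tip.
#' @param tree An `ape::phylo` tree with branch lengths (substitutions per
#'   codon). Foreground marks, if any, are carried in `tree$node.mark`.
#' @param mix Site-class table from [siteClassMix()].
#' @param kappa Transition/transversion ratio.
#' @param pi Codon equilibrium frequencies (length 61), or `"F3x4"` /
#'   `"uniform"` to estimate them from the alignment.
#' @param perSite If `TRUE`, also return the per-site log-likelihoods and
#'   per-site class posterior ingredients.
#' @return The log-likelihood (scalar), or a list with elements `lnL`,
#'   `siteLogLik` and `classLogLik` when `perSite = TRUE`.
#' @export
#' @examples
#' tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
#' aln <- CodonAlignment("g", c(
#'   A = "ATGAAA", B = "ATGAAG", C = "ATGGAA", D = "ATGGAG"
#' ))
#' codonLogLik(aln, tree, siteClassMix("M0", omega = 0.5), kappa = 2)
codonLogLik <- function(aln, tree, mix, kappa, pi = "F3x4", perSite = FALSE) {
  if (is.character(pi)) pi <- codonFrequencies(aln, pi)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  ctx <- .lik_context(aln, tree)
  bl <- ctx$tree$edge.length
  res <- .mix_loglik(ctx, mix, kappa, pi, bl, perPattern = TRUE)
  if (!perSite) return(res$lnL)
  list(
    lnL = res$lnL,
    siteLogLik = res$pat[ctx$map],
    classLogLik = res$classLogLik[ctx$map, , drop = FALSE]
  )
}
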