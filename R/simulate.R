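#' Simulate a codon alignment along a tree
#'
#' Generative twin of the likelihood engine: each codon site draws a
#' latent class from the site-class mixture, the root codon is drawn from
#' the equilibrium frequencies, and states evolve down each branch by
#' sampling from \eqn{P(t) = \exp(Qt)} with the class's background or
#' foreground omega according to the branch's mark. Only endpoint states
#' are needed, so transition-matrix draws are exact under the model.
#'
#' @param tree `ape::phylo` with branch lengths; foreground marks in
#'   `tree$node.mark` (see [markForeground()]) select the foreground omega.
#' @param mix Site-class table from [siteClassMix()].
#' @param kappa Transition/transversion ratio.
#' @param pi Codon equilibrium frequencies: `"uniform"` (default) or a
#'   61-vector.
#' @param nSites Number of codon sites to simulate.
#' @param seed Integer seed; mandatory for reproducibility.
#' @param geneId Identifier for the returned alignment.
#' @return A [CodonAlignment-class] with attribute `"siteClass"`: the
#'   1-based latent class label (from `mix$class`) of every site.
#' @export
#' @examples
#' tree <- ape::read.tree(text = "((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);")
#' aln <- simulateCodonAlignment(tree, siteClassMix("M0", omega = 0.3),
#'   kappa = 2, nSites = 50, seed = 7
#' )
simulateCodonAlignment <- function(tree, mix, kappa, pi = "uniform",
                                   nSites, seed, geneId = "sim") {
  stopifnot(inherits(tree, "phylo"), nSites >= 1)
  if (missing(seed)) stop("seed is mandatory")
  if (is.character(pi)) {
    pi <- switch(match.arg(pi, c("uniform")),
      uniform = rep(1 / 61, 61)
    )
  }
  stopifnot(length(pi) == 61, abs(sum(pi) - 1) < 1e-8)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  set.seed(as.integer(seed %% .Machine$integer.max))

  tr <- stats::reorder(tree, "postorder")
  marks <- .edge_marks(tr)
  # preorder = reversed postorder edge list
  edges <- rev(seq_len(nrow(tr$edge)))
  root <- tr$edge[nrow(tr$edge), 1]
  ntip <- length(tr$tip.label)
  nclass <- nrow(mix)

  cls <- sample.int(nclass, nSites, replace = TRUE, prob = mix$prop)
  states <- matrix(NA_integer_, ntip + tr$Nnode, nSites)
  states[root, ] <- sample.int(61, nSites, replace = TRUE, prob = pi)

  decs <- list()
  dec_for <- function(omega) {
    key <- sprintf("%.17g", omega)
    if (is.null(decs[[key]])) decs[[key]] <<- .codon_eigen(kappa, omega, pi, scaled = FALSE)
    decs[[key]]
  }
  scales <- .mix_scales(mix, kappa, pi)
  for (e in edges) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    fgEdge <- marks[e] > 0L
    t <- tr$edge.length[e] / scales[[if (fgEdge) "fg" else "bg"]]
    for (k in seq_len(nclass)) {
      sel <- which(cls == k)
      if (!length(sel)) next
      omega <- if (fgEdge) mix$omegaFg[k] else mix$omegaBg[k]
      P <- .codon_pmat(dec_for(omega), t)
      P <- P / rowSums(P)
      ps <- states[parent, sel]
      for (s in unique(ps)) {
        i <- sel[ps == s]
        states[child, i] <- sample.int(61, length(i), replace = TRUE, prob = P[s, ])
      }
    }
  }

  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1, function(z) {
    paste(.SENSE_CODONS[z], collapse = "")
  })
  names(seqs) <- tr$tip.label
  aln <- CodonAlignment(geneId, seqs)
  attr(aln, "siteClass") <- mix$class[cls]
  aln
}
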