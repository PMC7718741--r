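#' @import methods
NULL

#' CodonAlignment: one ortholog group's aligned codon sequences
#'
#' Stores an in-frame codon alignment as a character matrix of codon
#' triplets, one row per taxon and one column per codon site. Cells are
#' uppercase triplets over `A,C,G,T,-,N`; stop codons are disallowed except
#' where the cell contains a gap or ambiguity character. Construct with
#' [CodonAlignment()] or read from disk with [readCodonFasta()].
#'
#' @slot geneId Single gene/ortholog-group identifier.
#' @slot codons Character matrix (taxa x codon sites) with taxon rownames.
#' @name CodonAlignment-class
#' @aliases CodonAlignment-class
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(geneId = "character", codons = "matrix")
)

setValidity("CodonAlignment", function(object) {
  m <- object@codons
  if (length(object@geneId) != 1L) return("geneId must be a single string")
  if (!is.character(m)) return("codons must be a character matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    return("codon matrix needs unique taxon rownames")
  }
  if (ncol(m) > 0L) {
    ok <- grepl("^[ACGTN-]{3}$", m)
    if (!all(ok)) return("cells must be 3 characters over {A,C,G,T,-,N}")
    missing <- grepl("[-N]", m)
    if (any(m[!missing] %in% .STOP_CODONS)) {
      return("alignment contains in-frame stop codons")
    }
  }
  TRUE
})

#' Construct a CodonAlignment
#'
#' @param geneId Gene identifier.
#' @param codons Character matrix of codon triplets with taxon rownames, or
#'   a named character vector of in-frame nucleotide sequences (all the same
#'   length, divisible by 3) that will be split into codons.
#' @return A [CodonAlignment-class] object.
#' @export
#' @examples
#' aln <- CodonAlignment("g1", c(A = "ATGAAA", B = "ATGAAG"))
#' nCodonSites(aln)
CodonAlignment <- function(geneId, codons) {
  if (is.character(codons) && !is.matrix(codons)) {
    lens <- nchar(codons)
    if (length(unique(lens)) != 1L) stop("sequences differ in length")
    if (lens[1] %% 3 != 0L) {
      stop("sequence length ", lens[1], " is not divisible by 3")
    }
    n_sites <- lens[1] %/% 3
    nms <- names(codons)
    codons <- matrix(
      vapply(
        toupper(codons),
        function(s) substring(s, seq(1, lens[1], 3), seq(3, lens[1], 3)),
        character(n_sites)
      ),
      nrow = length(codons), ncol = n_sites, byrow = TRUE,
      dimnames = list(nms, NULL)
    )
  } else {
    codons <- toupper(codons)
  }
  new("CodonAlignment", geneId = as.character(geneId), codons = codons)
}

#' @describeIn CodonAlignment-class number of codon columns
#' @param x,object A `CodonAlignment`.
#' @export
nCodonSites <- function(x) ncol(x@codons)

#' @describeIn CodonAlignment-class taxon labels (row order)
#' @export
alignmentTaxa <- function(x) rownames(x@codons)

#' @describeIn CodonAlignment-class the codon matrix itself
#' @export
codonMatrix <- function(x) x@codons

#' @describeIn CodonAlignment-class gene identifier
#' @export
geneId <- function(x) x@geneId

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment '", object@geneId, "': ",
    nrow(object@codons), " taxa x ", ncol(object@codons), " codon sites\n",
    sep = ""
  )
  cat("  taxa: ", paste(utils::head(rownames(object@codons), 6), collapse = ", "),
    if (nrow(object@codons) > 6) ", ..." else "", "\n",
    sep = ""
  )
})

#' CodonFit: maximum-likelihood fit of a codon model
#'
#' Result container returned by [fitCodonModel()]. Site-class structure is a
#' data frame with columns `class`, `prop`, `omegaBg`, `omegaFg`; for
#' single-class models it has one row.
#'
#' @slot modelId One of `"M0"`, `"two_ratios"`, `"M1a"`, `"M2a"`,
#'   `"MA_null"`, `"MA"`.
#' @slot lnL Maximized log-likelihood.
#' @slot kappa Estimated transition/transversion ratio.
#' @slot pi Codon equilibrium frequencies used (length 61).
#' @slot classes Site-class mixture data frame.
#' @slot tree The (marked) `phylo` tree with fitted branch lengths.
#' @slot convergence Optimizer convergence code (0 = converged).
#' @slot boundary Character vector naming parameters that converged to a
#'   box boundary (e.g. `"omega2"` at 1, `"p2"` at 0).
#' @slot nStarts Number of optimizer starts used.
#' @name CodonFit-class
#' @exportClass CodonFit
setClass("CodonFit",
  representation(
    modelId = "character", lnL = "numeric", kappa = "numeric",
    pi = "numeric", classes = "data.frame", tree = "ANY",
    convergence = "integer", boundary = "character", nStarts = "integer"
  )
)

setValidity("CodonFit", function(object) {
  if (!object@modelId %in% .MODEL_IDS) return("unknown modelId")
  if (length(object@lnL) != 1L || !is.finite(object@lnL)) {
    return("lnL must be a single finite number")
  }
  cl <- object@classes
  need <- c("prop", "omegaBg", "omegaFg")
  if (!all(need %in% names(cl))) return("classes needs prop/omegaBg/omegaFg")
  if (abs(sum(cl$prop) - 1) > 1e-6) return("class proportions must sum to 1")
  TRUE
})

.MODEL_IDS <- c("M0", "two_ratios", "M1a", "M2a", "MA_null", "MA")

setMethod("show", "CodonFit", function(object) {
  cat("CodonFit [", object@modelId, "]  lnL = ",
    sprintf("%.6f", object@lnL),
    "  kappa = ", sprintf("%.4f", object@kappa), "\n",
    sep = ""
  )
  print(object@classes, row.names = FALSE, digits = 4)
  if (length(object@boundary)) {
    cat("  boundary:", paste(object@boundary, collapse = ", "), "\n")
  }
})

#' @describeIn CodonFit-class maximized log-likelihood
#' @param x A `CodonFit`.
#' @export
logLik.CodonFit <- function(object, ...) object@lnL

#' @describeIn CodonFit-class maximized log-likelihood
#' @export
fitLnL <- function(x) x@lnL

#' @describeIn CodonFit-class site-class mixture table
#' @export
siteClasses <- function(x) x@classes

#' @describeIn CodonFit-class foreground omega point estimate (branch and
#'   branch-site models: the selected-class foreground omega)
#' @export
omegaForeground <- function(x) {
  switch(x@modelId,
    M0 = x@classes$omegaFg[1],
    two_ratios = x@classes$omegaFg[1],
    MA = ,
    MA_null = x@classes$omegaFg[3],
    M2a = x@classes$omegaFg[3],
    stop("no single foreground omega for model ", x@modelId)
  )
}

#' @describeIn CodonFit-class background omega point estimate
#' @export
omegaBackground <- function(x) {
  switch(x@modelId,
    M0 = ,
    two_ratios = x@classes$omegaBg[1],
    MA = ,
    MA_null = ,
    M2a = ,
    M1a = x@classes$omegaBg[1],
    stop("no background omega for model ", x@modelId)
  )
}

#' SelectionTest: outcome of one gene x clade hypothesis test
#'
#' @slot geneId Gene identifier.
#' @slot cladeId Foreground clade id tested (0 for site models).
#' @slot modelPair Model pair label, e.g. `"M0_vs_two_ratios"`.
#' @slot lnLNull,lnLAlt Maximized log-likelihoods of the two hypotheses.
#' @slot statistic LRT statistic `max(0, 2 * (lnLAlt - lnLNull))`.
#' @slot df Chi-square degrees of freedom.
#' @slot pValue Upper-tail p-value.
#' @slot alphaUsed Significance level after any Bonferroni correction.
#' @slot candidate Is the gene a positive-selection candidate?
#' @slot omegaFg,omegaBg Foreground/background omega from the alternative
#'   fit (NA for site models' background-only quantities as applicable).
#' @slot positiveSites Data frame (`site`, `posterior`) of 1-based codon
#'   positions whose positive-class posterior exceeds the reporting
#'   threshold; empty unless the LRT is significant.
#' @name SelectionTest-class
#' @exportClass SelectionTest
setClass("SelectionTest",
  representation(
    geneId = "character", cladeId = "integer", modelPair = "character",
    lnLNull = "numeric", lnLAlt = "numeric", statistic = "numeric",
    df = "integer", pValue = "numeric", alphaUsed = "numeric",
    candidate = "logical", omegaFg = "numeric", omegaBg = "numeric",
    positiveSites = "data.frame"
  )
)

setValidity("SelectionTest", function(object) {
  if (object@statistic < 0) return("statistic must be >= 0")
  if (object@pValue < 0 || object@pValue > 1) return("pValue outside [0,1]")
  if (object@candidate && object@pValue >= object@alphaUsed) {
    return("candidate requires pValue < alphaUsed")
  }
  TRUE
})

setMethod("show", "SelectionTest", function(object) {
  cat("SelectionTest ", object@geneId,
    " (clade ", object@cladeId, ", ", object@modelPair, ")\n",
    "  2*dlnL = ", sprintf("%.4f", object@statistic),
    "  df = ", object@df,
    "  p = ", sprintf("%.4g", object@pValue),
    "  candidate: ", object@candidate, "\n",
    sep = ""
  )
  if (nrow(object@positiveSites)) {
    cat("  positively selected sites:",
      paste(sprintf("%d(%.3f)", object@positiveSites$site,
        object@positiveSites$posterior
      ), collapse = " "), "\n"
    )
  }
})

#' @describeIn SelectionTest-class is the gene a candidate?
#' @param x A `SelectionTest`.
#' @export
isCandidate <- function(x) x@candidate

#' @describeIn SelectionTest-class positively selected codon positions
#' @export
positiveSites <- function(x) x@positiveSites

#' @describeIn SelectionTest-class LRT p-value
#' @export
pValue <- function(x) x@pValue
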