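# Gene admission filters, per-gene tree pruning, foreground marking,
# complete-ortholog selection and gene-tree monophyly checks.

.FLAG_REASONS <- c(
  "duplicate_taxon", "below_min_foreground", "below_min_background",
  "foreground_not_monophyletic_species_tree",
  "foreground_not_monophyletic_gene_tree",
  "no_foreground_taxon", "fit_failure", "read_error"
)

.gene_flag <- function(geneId, reason) {
  stopifnot(reason %in% .FLAG_REASONS)
  data.frame(gene_id = geneId, reason = reason, stringsAsFactors = FALSE)
}

#' Admit or reject an alignment for testing
#'
#' An alignment passes for a given foreground clade iff it has at least
#' `minForeground` taxa labelled with that clade id and at least
#' `minBackground` taxa with any other label. Both thresholds default to
#' 0, so every duplicate-free alignment passes by default. (Duplicate taxa
#' are impossible inside a valid [CodonAlignment-class]; they are flagged
#' at read time.)
#'
#' @param aln A [CodonAlignment-class].
#' @param labels Named integer clade ids over the species-tree taxa
#'   ([readBranchLabels()]).
#' @param cladeId Foreground clade id (>= 1) under test.
#' @param minForeground,minBackground Minimum taxon counts.
#' @return List with `admitted` (logical) and, when rejected, `flag` (a
#'   one-row data frame `gene_id`, `reason`).
#' @export
admitGene <- function(aln, labels, cladeId, minForeground = 0L, minBackground = 0L) {
  taxa <- alignmentTaxa(aln)
  lab <- labels[taxa]
  lab[is.na(lab)] <- 0L
  nFg <- sum(lab == cladeId)
  nBg <- sum(lab != cladeId)
  if (nFg < minForeground) {
    return(list(admitted = FALSE, flag = .gene_flag(geneId(aln), "below_min_foreground")))
  }
  if (nBg < minBackground) {
    return(list(admitted = FALSE, flag = .gene_flag(geneId(aln), "below_min_background")))
  }
  list(admitted = TRUE, flag = NULL)
}

#' Prune a species tree down to an alignment's taxa
#'
#' Restriction of the input topology: the leaf set of the result equals
#' `taxa`, every bipartition of the result is the restriction of an input
#' bipartition, degree-2 nodes are suppressed with their incident edge
#' lengths summed, so all surviving leaf-to-leaf path lengths are
#' preserved.
#'
#' @param tree `ape::phylo`.
#' @param taxa Subset of `tree$tip.label` of size >= 2.
#' @return Pruned `ape::phylo`.
#' @export
pruneToAlignment <- function(tree, taxa) {
  taxa <- unique(taxa)
  bad <- setdiff(taxa, tree$tip.label)
  if (length(bad)) stop("taxa not in tree: ", paste(bad, collapse = ", "))
  if (length(taxa) < 2L) stop("pruning needs at least 2 taxa")
  if (setequal(taxa, tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}

# Does `taxa` form one side of a bipartition of the unrooted tree?
# TRUE also for a single leaf or the full leaf set.
.is_monophyletic_unrooted <- function(tree, taxa) {
  taxa <- intersect(taxa, tree$tip.label)
  n <- length(tree$tip.label)
  if (length(taxa) == 0L) return(FALSE)
  if (length(taxa) == 1L || length(taxa) == n) return(TRUE)
  if (length(taxa) == n - 1L) return(TRUE) # complement is a single leaf
  ape::is.monophyletic(tree, taxa) ||
    ape::is.monophyletic(tree, setdiff(tree$tip.label, taxa))
}

#' Mark the foreground clade on a (pruned) tree
#'
#' If the foreground taxa present in the tree are monophyletic, the marks
#' are written to `tree$node.mark` (mark of the edge above each node):
#' with `scope = "clade"` every branch of the clade including its stem
#' receives the clade id; with `scope = "stem"` only the stem branch does.
#' If they are not monophyletic the gene cannot be tested against this
#' species topology and the verdict says so.
#'
#' @param tree `ape::phylo` (typically from [pruneToAlignment()]).
#' @param labels Named clade ids over species-tree taxa.
#' @param cladeId Foreground clade id (>= 1).
#' @param scope `"clade"` (default) or `"stem"`.
#' @return List with `tree` (marked, possibly rerooted so the foreground
#'   forms a clade), `monophyletic` (logical) and `flag` (data frame or
#'   NULL).
#' @export
markForeground <- function(tree, labels, cladeId, scope = c("clade", "stem")) {
  scope <- match.arg(scope)
  fg <- intersect(names(labels)[labels == cladeId], tree$tip.label)
  if (length(fg) == 0L) {
    return(list(
      tree = tree, monophyletic = FALSE,
      flag = .gene_flag(NA_character_, "no_foreground_taxon")
    ))
  }
  if (!.is_monophyletic_unrooted(tree, fg)) {
    return(list(
      tree = tree, monophyletic = FALSE,
      flag = .gene_flag(NA_character_, "foreground_not_monophyletic_species_tree")
    ))
  }
  ntip <- length(tree$tip.label)
  # Root outside the foreground so it forms a clade below one node; for a
  # reversible model the root placement does not change the likelihood.
  if (length(fg) < ntip) {
    bg1 <- setdiff(tree$tip.label, fg)[1]
    if (!ape::is.monophyletic(tree, fg)) {
      tree <- ape::root(tree, outgroup = bg1, resolve.root = TRUE)
    }
  }
  ntot <- ntip + tree$Nnode
  marks <- integer(ntot)
  if (length(fg) == 1L) {
    mrca <- match(fg, tree$tip.label)
  } else if (length(fg) == ntip) {
    mrca <- ntip + 1L
  } else {
    mrca <- ape::getMRCA(tree, fg)
  }
  if (scope == "stem" || length(fg) == 1L) {
    marks[mrca] <- cladeId
  } else {
    desc <- .descendant_nodes(tree, mrca)
    marks[c(mrca, desc)] <- cladeId
  }
  tree$node.mark <- marks
  list(tree = tree, monophyletic = TRUE, flag = NULL)
}

# all nodes strictly below `node`
.descendant_nodes <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  if (!length(kids)) return(integer())
  c(kids, unlist(lapply(kids, .descendant_nodes, tree = tree)))
}

#' Select complete ortholog groups
#'
#' Gene ids of the alignments whose taxon set equals `species` exactly —
#' the groups usable for reconstructing a species phylogeny from a
#' concatenated alignment.
#'
#' @param alignments List of [CodonAlignment-class] objects.
#' @param species Character vector of required taxa.
#' @return Character vector of gene ids (possibly empty).
#' @export
selectCompleteOrthologs <- function(alignments, species) {
  ids <- vapply(alignments, function(a) {
    if (setequal(alignmentTaxa(a), species)) geneId(a) else NA_character_
  }, character(1))
  unname(ids[!is.na(ids)])
}

#' Build a gene tree by neighbor joining
#'
#' Pairwise nucleotide p-distances are computed on the concatenated codon
#' columns, excluding — pairwise — any site where either sequence has a
#' gap or ambiguity, and passed to neighbor joining. Deterministic for a
#' fixed input; identical sequences give zero distances and a valid
#' zero-length tree.
#'
#' @param aln A [CodonAlignment-class] with >= 3 taxa.
#' @return Unrooted `ape::phylo`.
#' @export
buildGeneTree <- function(aln) {
  taxa <- alignmentTaxa(aln)
  if (length(taxa) < 3L) stop("gene tree needs at least 3 taxa")
  cod <- codonMatrix(aln)
  nucs <- do.call(cbind, lapply(seq_len(ncol(cod)), function(j) {
    do.call(rbind, strsplit(cod[, j], ""))
  }))
  rownames(nucs) <- taxa
  known <- nucs %in% .NUC
  dim(known) <- dim(nucs)
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- known[i, ] & known[j, ]
      D[i, j] <- D[j, i] <- if (any(ok)) {
        mean(nucs[i, ok] != nucs[j, ok])
      } else {
        0
      }
    }
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Check clade monophyly on a gene tree
#'
#' The foreground taxa present in the gene tree are monophyletic iff they
#' form one complete side of some bipartition of the unrooted tree (a
#' single leaf and the full leaf set count as monophyletic).
#'
#' @param tree `ape::phylo` (rooting is ignored).
#' @param foregroundTaxa Character vector; at least one must be a leaf.
#' @return Logical verdict.
#' @export
checkMonophyly <- function(tree, foregroundTaxa) {
  present <- intersect(foregroundTaxa, tree$tip.label)
  if (length(present) == 0L) stop("no foreground taxon present in the gene tree")
  .is_monophyletic_unrooted(tree, present)
}
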