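# Reading alignments, trees and branch-label files.

# condition helpers so the pipeline can turn per-gene problems into flags
.gene_error <- function(class, msg, gene = NULL) {
  stop(structure(
    class = c(class, "selwideGeneError", "error", "condition"),
    list(message = msg, call = sys.call(-1), gene = gene)
  ))
}

#' Read a codon alignment from FASTA, resolving names to tree taxa
#'
#' Each FASTA record name is resolved to the unique tree taxon whose label
#' occurs as a substring of the record name (exact equality counts as an
#' occurrence) — the "common denominator" between alignment names and tree
#' labels. Nucleotides are upper-cased; sequences must share a length
#' divisible by three.
#'
#' @param path FASTA file (wrapped or unwrapped records).
#' @param treeTaxa Nonempty character vector of tree taxon labels.
#' @param geneId Gene identifier; defaults to the file name without
#'   extension.
#' @return A [CodonAlignment-class] keyed by resolved taxon labels.
#'
#' Errors are signalled with classed conditions: `frameError` (length not
#' divisible by 3), `resolutionError` (a record matches zero or several
#' taxa), `duplicateTaxonError` (two records resolve to the same taxon).
#' @export
readCodonFasta <- function(path, treeTaxa, geneId = NULL) {
  stopifnot(file.exists(path), length(treeTaxa) > 0)
  if (is.null(geneId)) {
    geneId <- sub("\\.[^.]*$", "", basename(path))
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) .gene_error("frameError", "empty FASTA file", geneId)
  lens <- Biostrings::width(seqs)
  if (length(unique(lens)) != 1L) {
    .gene_error("frameError", paste0(geneId, ": sequences differ in length"), geneId)
  }
  if (lens[1] %% 3 != 0L) {
    .gene_error("frameError", paste0(
      geneId, ": alignment length ", lens[1], " is not divisible by 3"
    ), geneId)
  }
  recs <- names(seqs)
  resolved <- vapply(recs, function(nm) {
    hits <- treeTaxa[vapply(treeTaxa, function(tx) {
      grepl(tx, nm, fixed = TRUE)
    }, logical(1))]
    if (length(hits) == 0L) {
      .gene_error("resolutionError", paste0(
        geneId, ": record '", nm, "' matches no tree taxon"
      ), geneId)
    }
    if (length(hits) > 1L) {
      .gene_error("resolutionError", paste0(
        geneId, ": record '", nm, "' matches several tree taxa: ",
        paste(hits, collapse = ", ")
      ), geneId)
    }
    hits
  }, character(1))
  if (anyDuplicated(resolved)) {
    dup <- unique(resolved[duplicated(resolved)])
    .gene_error("duplicateTaxonError", paste0(
      geneId, ": multiple records resolve to taxon ",
      paste(dup, collapse = ", ")
    ), geneId)
  }
  x <- toupper(as.character(seqs))
  names(x) <- resolved
  CodonAlignment(geneId, x)
}

#' Read a Newick tree
#'
#' Parses one Newick string. Branch lengths and internal labels are
#' preserved. An unrooted (basal trifurcation) input is kept as read — the
#' basal multifurcation acts as an arbitrary root — with a message.
#'
#' @param path File containing a single Newick tree.
#' @return An `ape::phylo`.
#' @export
readNewickTree <- function(path) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) {
    stop("expected a single Newick tree, found ", length(tree))
  }
  if (is.null(tree) || !inherits(tree, "phylo")) stop("Newick parse failure: ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in tree: ",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")
    )
  }
  if (!ape::is.rooted(tree)) {
    message("input tree is unrooted; its basal multifurcation is used as the root")
  }
  tree
}

#' Write a tree as Newick
#'
#' @param tree `ape::phylo`.
#' @param path Output file; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
writeNewickTree <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read a branch-label file
#'
#' One `taxon integer` pair per line (whitespace- or comma-separated);
#' `#` comments and blank lines are ignored. Integer 0 marks background,
#' integers >= 1 name foreground clades; taxa absent from the file default
#' to 0. Several distinct foreground ids trigger one scan per clade in
#' [runSelectionScan()].
#'
#' @param path Label file.
#' @param tree `ape::phylo` whose tip labels the taxa must belong to.
#' @return Named integer vector over all tree tips (the clade id of each).
#' @export
readBranchLabels <- function(path, tree) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  labels <- stats::setNames(
    integer(length(tree$tip.label)), tree$tip.label
  )
  for (ln in lines) {
    tok <- strsplit(ln, "[,[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) != 2L) stop("malformed branch-label line: '", ln, "'")
    taxon <- tok[1]
    if (!taxon %in% tree$tip.label) {
      stop("branch-label taxon not in tree: '", taxon, "'")
    }
    if (!grepl("^[0-9]+$", tok[2])) {
      stop("branch label for '", taxon, "' is not a nonnegative integer: '", tok[2], "'")
    }
    labels[taxon] <- as.integer(tok[2])
  }
  labels
}
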