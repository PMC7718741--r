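# codeml (PAML 4.9) interoperability: control-file generation, marked
# Newick output, and main-output parsing.

.CTL_SETTINGS <- list(
  branch = list(
    null = c(model = 0, NSsites = 0),
    alt = c(model = 2, NSsites = 0)
  ),
  site = list(
    null = c(model = 0, NSsites = 1),
    alt = c(model = 0, NSsites = 2)
  ),
  `branch-site` = list(
    null = c(model = 2, NSsites = 2, fix_omega = 1, omega = 1),
    alt = c(model = 2, NSsites = 2, fix_omega = 0)
  )
)

# per-model-id aliases onto the three pairs
.CTL_MODEL_ALIAS <- c(
  M0 = "branch:null", two_ratios = "branch:alt",
  M1a = "site:null", M2a = "site:alt",
  MA_null = "branch-site:null", MA = "branch-site:alt"
)

#' Generate a codeml control file
#'
#' Emits the `key = value` control file driving codeml for one hypothesis
#' of a model pair. Fixed settings in every file: `seqtype = 1`,
#' `CodonFreq = 2` (F3x4), `cleandata = 0`, `fix_kappa = 0` with initial
#' `kappa = 2`. Hypothesis-specific settings: branch null
#' `model = 0, NSsites = 0`; branch alt `model = 2, NSsites = 0`; site
#' null `model = 0, NSsites = 1`; site alt `model = 0, NSsites = 2`;
#' branch-site null `model = 2, NSsites = 2, fix_omega = 1, omega = 1`;
#' branch-site alt `model = 2, NSsites = 2, fix_omega = 0`. Output is
#' byte-stable (LF line endings) for fixed arguments.
#'
#' @param model `"branch"`, `"site"`, `"branch-site"`, or a model id
#'   (`"M0"`, `"two_ratios"`, `"M1a"`, `"M2a"`, `"MA_null"`, `"MA"`, in
#'   which case `hypothesis` is implied).
#' @param hypothesis `"null"` or `"alt"`.
#' @param seqfile,treefile,outfile Paths written into the control file.
#' @param path If non-NULL, the text is also written to this file.
#' @return The control-file text (single string), invisibly when `path`
#'   is given.
#' @export
codemlControlFile <- function(model, hypothesis = c("null", "alt"),
                              seqfile, treefile, outfile, path = NULL) {
  if (model %in% names(.CTL_MODEL_ALIAS)) {
    parts <- strsplit(.CTL_MODEL_ALIAS[[model]], ":")[[1]]
    model <- parts[1]
    hypothesis <- parts[2]
  } else {
    hypothesis <- match.arg(hypothesis)
  }
  if (!model %in% names(.CTL_SETTINGS)) stop("unknown model id: ", model)
  hyp <- .CTL_SETTINGS[[model]][[hypothesis]]
  kv <- c(
    seqfile = seqfile, treefile = treefile, outfile = outfile,
    noisy = 0, verbose = 0, runmode = 0,
    seqtype = 1, CodonFreq = 2, clock = 0, aaDist = 0,
    hyp["model"], hyp["NSsites"],
    icode = 0, fix_kappa = 0, kappa = 2,
    if ("fix_omega" %in% names(hyp)) hyp["fix_omega"] else c(fix_omega = 0),
    if ("omega" %in% names(hyp)) hyp["omega"] else c(omega = 0.5),
    cleandata = 0
  )
  text <- paste0(paste(names(kv), "=", kv, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, "wb") # LF endings on every platform
    writeLines(text, con, sep = "")
    close(con)
    return(invisible(text))
  }
  text
}

#' Write a PAML marked Newick string
#'
#' Annotates the foreground with PAML's branch labels: with
#' `scope = "clade"` the clade's most recent common ancestor is tagged
#' `$1` (the whole subtree is foreground); with `scope = "stem"` the
#' node is tagged `#1` (only the stem branch). A single-leaf foreground is
#' always tagged `#1` on its terminal branch.
#'
#' @param tree Marked `ape::phylo` from [markForeground()].
#' @param cladeId Clade id whose marks are emitted (written as label 1 for
#'   codeml, which tests one foreground at a time).
#' @param scope `"clade"` or `"stem"`.
#' @param path Optional output file.
#' @return Newick text.
#' @export
writeMarkedNewick <- function(tree, cladeId = 1L, scope = c("clade", "stem"),
                              path = NULL) {
  scope <- match.arg(scope)
  marks <- tree$node.mark
  if (is.null(marks) || !any(marks == cladeId)) {
    stop("tree carries no branch marked with clade ", cladeId)
  }
  ntip <- length(tree$tip.label)
  marked <- which(marks == cladeId)
  # topmost marked node: the marked node whose parent is unmarked (or root)
  parent_of <- function(n) {
    p <- tree$edge[tree$edge[, 2] == n, 1]
    if (length(p)) p else NA_integer_
  }
  tops <- marked[vapply(marked, function(n) {
    p <- parent_of(n)
    is.na(p) || !(p %in% marked)
  }, logical(1))]
  top <- tops[1]
  tag <- if (top <= ntip && length(marked) == 1L) "#1" else {
    if (scope == "clade") "$1" else "#1"
  }
  tr <- tree
  if (top <= ntip) {
    tr$tip.label[top] <- paste0(tr$tip.label[top], " ", tag)
  } else {
    if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
    tr$node.label[top - ntip] <- tag
  }
  tr$node.mark <- NULL
  s <- ape::write.tree(tr)
  # ape quotes labels containing spaces; strip the quotes PAML dislikes
  s <- gsub("'", "", s, fixed = TRUE)
  s <- gsub("_(\\$|#)1", " \\11", s)
  if (!is.null(path)) {
    con <- file(path, "wb")
    writeLines(s, con, sep = "\n")
    close(con)
    return(invisible(s))
  }
  s
}

#' Parse a codeml main output file
#'
#' Extracts from a PAML 4.9 main result file: the maximized
#' log-likelihood from the `lnL(...)...` line (the first number after the
#' closing parenthesis), the foreground/background omega estimates from
#' the model's omega table (`w (dN/dS) for branches`, or the site-class
#' `MLEs` table with `background w` / `foreground w` rows, or the
#' `omega (dN/dS)` line of one-ratio fits), and the Bayes Empirical Bayes
#' positively selected sites with posterior strictly greater than
#' `bebThreshold`. Trailing whitespace and the `*`/`**` significance
#' marks are tolerated; an absent BEB block yields an empty site table
#' (normal for null fits).
#'
#' @param x Path to a codeml output file, or its text as a character
#'   vector of lines.
#' @param bebThreshold Posterior threshold for retaining BEB sites
#'   (default 0.9, strictly greater).
#' @return List with `lnL`, `omega` (named numeric; elements among
#'   `omega`, `background`, `foreground`), and `bebSites` (data frame
#'   `site`, `aminoAcid`, `posterior`).
#' @export
parseCodemlOutput <- function(x, bebThreshold = 0.9) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  lnl_line <- grep("^\\s*lnL", lines, value = TRUE)
  if (length(lnl_line) == 0L) stop("no lnL line found in codeml output")
  m <- regmatches(
    lnl_line[1],
    regexpr("\\):\\s*(-?[0-9]+\\.?[0-9]*)", lnl_line[1])
  )
  if (!length(m)) stop("malformed lnL line: ", lnl_line[1])
  lnL <- as.numeric(sub("\\):\\s*", "", m))

  omega <- c()
  wb <- grep("w \\(dN/dS\\) for branches:", lines, value = TRUE)
  if (length(wb)) {
    vals <- as.numeric(strsplit(trimws(sub(".*branches:", "", wb[1])), "\\s+")[[1]])
    omega <- c(background = vals[1], foreground = vals[length(vals)])
  }
  bg <- grep("^\\s*background w", lines, value = TRUE)
  fg <- grep("^\\s*foreground w", lines, value = TRUE)
  if (length(bg) && length(fg)) {
    getv <- function(l) as.numeric(strsplit(trimws(sub("^.*? w", "", l)), "\\s+")[[1]])
    bgv <- getv(bg[1])
    fgv <- getv(fg[1])
    omega <- c(background = bgv[1], foreground = fgv[length(fgv)])
  }
  w1 <- grep("omega \\(dN/dS\\)\\s*=", lines, value = TRUE)
  if (!length(omega) && length(w1)) {
    omega <- c(omega = as.numeric(sub(".*=\\s*", "", w1[1])))
  }
  wrow <- grep("^\\s*w:\\s", lines, value = TRUE)
  if (!length(omega) && length(wrow)) {
    vals <- as.numeric(strsplit(trimws(sub("^\\s*w:", "", wrow[1])), "\\s+")[[1]])
    omega <- c(background = vals[1], foreground = vals[length(vals)])
  }

  beb <- data.frame(site = integer(), aminoAcid = character(), posterior = numeric())
  start <- grep("Bayes Empirical Bayes", lines)
  if (length(start)) {
    block <- lines[start[1]:length(lines)]
    rows <- grep("^\\s*[0-9]+\\s+[A-Z*]\\s+[0-9]*\\.[0-9]+\\**\\s*$", block, value = TRUE)
    if (length(rows)) {
      parts <- strsplit(trimws(rows), "\\s+")
      beb <- data.frame(
        site = vapply(parts, function(p) as.integer(p[1]), integer(1)),
        aminoAcid = vapply(parts, function(p) p[2], character(1)),
        posterior = vapply(parts, function(p) as.numeric(sub("\\*+$", "", p[3])), numeric(1))
      )
      beb <- beb[beb$posterior > bebThreshold, , drop = FALSE]
      rownames(beb) <- NULL
    }
  }
  list(lnL = lnL, omega = omega, bebSites = beb)
}
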