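# End-to-end scan: admit genes, prune and mark trees, fit null/alt models,
# test, correct, classify, and write outputs.

#' Configuration for a selection scan
#'
#' Collects and validates every setting of [runSelectionScan()].
#'
#' @param alignmentDir Directory of codon-aligned FASTA files (one
#'   ortholog group per file; extensions fa/fas/fasta/fna).
#' @param treePath Newick species tree containing all taxa.
#' @param branchLabelPath Branch-label file (`taxon integer` lines);
#'   required for branch and branch-site models.
#' @param model `"branch"`, `"site"` or `"branch-site"`.
#' @param minForeground,minBackground Admission thresholds (default 0).
#' @param alpha Significance level (default 0.05).
#' @param siteThreshold Posterior threshold for reporting selected codons
#'   (default 0.9).
#' @param bonferroni Correct `alpha` by the number of foreground clades
#'   tested in the run?
#' @param geneTrees Build per-gene NJ trees and flag genes whose
#'   foreground clade is not monophyletic in them?
#' @param dndsOut Also collect foreground/background omega per gene
#'   (branch and branch-site models)?
#' @param threads Maximum parallel workers (forked; default 1).
#' @param backend `"internal"` (built-in engine) or `"codeml"` (drive the
#'   external PAML binary, which must be on the PATH).
#' @param seed Global seed; per-gene seeds are derived from it and the
#'   gene id, so results are identical for any thread count.
#' @param foregroundScope `"clade"` or `"stem"` branch marking.
#' @param fixBranchLengths Reuse branch lengths from a one-ratio (M0) fit
#'   in the alternative/null model fits instead of re-estimating them per
#'   model (speed-up; default FALSE).
#' @param nStarts Optimizer starts per fit (default 3).
#' @param writeTrees Also write each gene's pruned (marked) tree as a
#'   Newick file under `trees/` in the output directory?
#' @param customCtl For `model = "custom"` only (requires
#'   `backend = "codeml"`): list with elements `null` and `alt` (paths to
#'   user-written codeml control-file templates whose `seqfile`,
#'   `treefile` and `outfile` lines are rewritten per gene) and `df`
#'   (LRT degrees of freedom).
#' @return A validated list of class `selwideConfig`.
#' @export
scanConfig <- function(alignmentDir, treePath, branchLabelPath = NULL,
                       model = c("branch", "site", "branch-site", "custom"),
                       minForeground = 0L, minBackground = 0L,
                       alpha = 0.05, siteThreshold = 0.9,
                       bonferroni = FALSE, geneTrees = FALSE, dndsOut = FALSE,
                       threads = 1L, backend = c("internal", "codeml"),
                       seed = 1L, foregroundScope = c("clade", "stem"),
                       fixBranchLengths = FALSE, nStarts = 3L,
                       writeTrees = FALSE, customCtl = NULL) {
  model <- match.arg(model)
  backend <- match.arg(backend)
  foregroundScope <- match.arg(foregroundScope)
  stopifnot(dir.exists(alignmentDir), file.exists(treePath))
  if (model != "site" && is.null(branchLabelPath)) {
    stop("branch, branch-site and custom models require a branch-label file")
  }
  if (model == "custom") {
    if (backend != "codeml") {
      stop("model = 'custom' requires backend = 'codeml'")
    }
    if (is.null(customCtl) || !all(c("null", "alt", "df") %in% names(customCtl))) {
      stop("model = 'custom' requires customCtl = list(null =, alt =, df =)")
    }
    stopifnot(
      file.exists(customCtl$null), file.exists(customCtl$alt),
      customCtl$df >= 1
    )
  }
  stopifnot(alpha > 0, alpha < 1, threads >= 1)
  structure(
    list(
      alignmentDir = alignmentDir, treePath = treePath,
      branchLabelPath = branchLabelPath, model = model,
      minForeground = as.integer(minForeground),
      minBackground = as.integer(minBackground),
      alpha = alpha, siteThreshold = siteThreshold,
      bonferroni = isTRUE(bonferroni), geneTrees = isTRUE(geneTrees),
      dndsOut = isTRUE(dndsOut), threads = as.integer(threads),
      backend = backend, seed = as.integer(seed),
      foregroundScope = foregroundScope,
      fixBranchLengths = isTRUE(fixBranchLengths),
      nStarts = as.integer(nStarts),
      writeTrees = isTRUE(writeTrees), customCtl = customCtl
    ),
    class = "selwideConfig"
  )
}

# deterministic 31-bit seed from the global seed and a gene id
.gene_seed <- function(seed, geneId, cladeId = 0L) {
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(paste0(geneId, ":", cladeId))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

.list_alignment_files <- function(dir) {
  sort(list.files(dir, pattern = "\\.(fa|fas|fasta|fna)$", full.names = TRUE))
}

# Process one gene for one clade. Returns list(outcome=SelectionTest|NULL,
# flag=data.frame|NULL, dnds=..., monophyly=..., treeText=...). Never throws.
.scan_gene <- function(file, cfg, tree, labels, cladeId, alphaUsed, pair) {
  gid <- sub("\\.[^.]*$", "", basename(file))
  flag_out <- function(reason) {
    list(
      outcome = NULL, flag = .gene_flag(gid, reason), dnds = NULL,
      monophyly = NULL, treeText = NULL
    )
  }
  aln <- tryCatch(
    readCodonFasta(file, tree$tip.label, geneId = gid),
    duplicateTaxonError = function(e) e,
    error = function(e) e
  )
  if (inherits(aln, "condition")) {
    reason <- if (inherits(aln, "duplicateTaxonError")) "duplicate_taxon" else "read_error"
    return(flag_out(reason))
  }
  adm <- admitGene(aln, labels, cladeId, cfg$minForeground, cfg$minBackground)
  if (!adm$admitted) {
    return(list(
      outcome = NULL, flag = adm$flag, dnds = NULL, monophyly = NULL,
      treeText = NULL
    ))
  }
  gtree <- tryCatch(pruneToAlignment(tree, alignmentTaxa(aln)), error = function(e) e)
  if (inherits(gtree, "error")) return(flag_out("read_error"))

  monoFlag <- NULL
  if (cfg$model != "site") {
    mk <- markForeground(gtree, labels, cladeId, scope = cfg$foregroundScope)
    if (!mk$monophyletic) {
      f <- mk$flag
      f$gene_id <- gid
      return(list(
        outcome = NULL, flag = f, dnds = NULL, monophyly = NULL,
        treeText = NULL
      ))
    }
    gtree <- mk$tree
    if (cfg$geneTrees && length(alignmentTaxa(aln)) >= 3) {
      fg <- names(labels)[labels == cladeId]
      nj <- tryCatch(buildGeneTree(aln), error = function(e) NULL)
      if (!is.null(nj) && !checkMonophyly(nj, fg)) {
        monoFlag <- .gene_flag(gid, "foreground_not_monophyletic_gene_tree")
      }
    }
  }

  treeText <- if (cfg$writeTrees) {
    if (cfg$model != "site" && !is.null(gtree$node.mark)) {
      writeMarkedNewick(gtree, cladeId, scope = cfg$foregroundScope)
    } else {
      writeNewickTree(gtree)
    }
  } else {
    NULL
  }

  gseed <- .gene_seed(cfg$seed, gid, cladeId)
  if (cfg$model == "custom") {
    res <- tryCatch(.run_custom_pair(aln, gtree, cfg, cladeId), error = function(e) e)
    if (inherits(res, "error")) {
      out <- flag_out("fit_failure")
      out$monophyly <- monoFlag
      return(out)
    }
    lr <- lrTest(res$lnLNull, res$lnLAlt, cfg$customCtl$df)
    outcome <- new("SelectionTest",
      geneId = gid, cladeId = as.integer(cladeId), modelPair = "custom",
      lnLNull = res$lnLNull, lnLAlt = res$lnLAlt,
      statistic = lr$statistic, df = as.integer(cfg$customCtl$df),
      pValue = lr$pValue, alphaUsed = alphaUsed,
      candidate = lr$pValue < alphaUsed,
      omegaFg = NA_real_, omegaBg = NA_real_,
      positiveSites = data.frame(site = integer(), posterior = numeric())
    )
    return(list(
      outcome = outcome, flag = NULL, dnds = NULL, monophyly = monoFlag,
      treeText = treeText
    ))
  }
  res <- tryCatch(
    {
      if (cfg$backend == "codeml") {
        .fit_pair_codeml(aln, gtree, cfg, pair, cladeId)
      } else {
        .fit_pair_internal(aln, gtree, cfg, pair, gseed)
      }
    },
    error = function(e) e
  )
  if (inherits(res, "error")) {
    out <- flag_out("fit_failure")
    out$monophyly <- monoFlag
    return(out)
  }
  bebSites <- if (!is.null(res$beb) && nrow(res$beb)) {
    data.frame(site = res$beb$site, posterior = res$beb$posterior)
  } else if (!is.null(res$beb)) {
    data.frame(site = integer(), posterior = numeric())
  } else {
    NULL
  }
  outcome <- classifyOutcome(
    gid, cladeId, res$null, res$alt, aln,
    alphaUsed = alphaUsed, siteThreshold = cfg$siteThreshold,
    sites = bebSites
  )
  dnds <- NULL
  if (cfg$dndsOut && cfg$model != "site") {
    dnds <- data.frame(
      gene_id = gid, clade_id = cladeId,
      omega_foreground = outcome@omegaFg, omega_background = outcome@omegaBg
    )
  }
  list(
    outcome = outcome, flag = NULL, dnds = dnds, monophyly = monoFlag,
    treeText = treeText
  )
}

# Custom model pair through the external backend: the user's two control
# files are templated per gene (seqfile/treefile/outfile rewritten),
# codeml is run for each, and the lnL values are extracted.
.run_custom_pair <- function(aln, gtree, cfg, cladeId) {
  if (Sys.which("codeml") == "") stop("codeml binary not found on PATH")
  wd <- tempfile("codeml_custom_")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  seqfile <- file.path(wd, "gene.phy")
  .write_paml_seq(aln, seqfile)
  treefile <- file.path(wd, "gene.trees")
  if (!is.null(gtree$node.mark)) {
    writeMarkedNewick(gtree, cladeId, scope = cfg$foregroundScope, path = treefile)
  } else {
    writeLines(ape::write.tree(gtree), treefile)
  }
  runOne <- function(template, tag) {
    outfile <- file.path(wd, paste0("out_", tag, ".txt"))
    ctl <- readLines(template, warn = FALSE)
    drop <- grepl("^\\s*(seqfile|treefile|outfile)\\s*=", ctl)
    ctl <- c(
      paste("seqfile =", seqfile),
      paste("treefile =", treefile),
      paste("outfile =", outfile),
      ctl[!drop]
    )
    ctlPath <- file.path(wd, paste0(tag, ".ctl"))
    writeLines(ctl, ctlPath)
    owd <- setwd(wd)
    on.exit(setwd(owd), add = TRUE)
    system2("codeml", basename(ctlPath), stdout = FALSE, stderr = FALSE)
    setwd(owd)
    parseCodemlOutput(outfile)$lnL
  }
  list(
    lnLNull = runOne(cfg$customCtl$null, "null"),
    lnLAlt = runOne(cfg$customCtl$alt, "alt")
  )
}

.fit_pair_internal <- function(aln, gtree, cfg, pair, gseed) {
  ftree <- gtree
  if (cfg$fixBranchLengths) {
    m0 <- fitCodonModel(aln, gtree, "M0",
      nStarts = 1L, seed = gseed,
      control = list(maxit = 500)
    )
    ftree <- m0@tree
  }
  fitNull <- fitCodonModel(aln, ftree, pair$null,
    nStarts = cfg$nStarts,
    seed = gseed, fixBranchLengths = cfg$fixBranchLengths
  )
  # the alternative nests the null: start from the null's solution
  cln <- fitNull@classes
  startAlt <- switch(pair$alt,
    two_ratios = list(
      kappa = fitNull@kappa, omega = cln$omegaBg[1],
      omegaFg = max(cln$omegaBg[1], 1)
    ),
    M2a = {
      p0 <- 0.95 * cln$prop[1]
      p1 <- 0.95 * (1 - cln$prop[1])
      list(
        kappa = fitNull@kappa, s1 = p0, s2 = p1 / (1 - p0),
        omega0 = max(cln$omegaBg[1], 1e-3), omega2 = 2
      )
    },
    MA = {
      # proportions of the null fit transfer one-to-one
      p0 <- min(max(cln$prop[1], 1e-4), 1 - 2e-4)
      p1 <- min(max(cln$prop[2] / (1 - p0), 1e-4), 1 - 1e-4)
      list(
        kappa = fitNull@kappa, s1 = p0, s2 = p1,
        omega0 = max(cln$omegaBg[1], 1e-3), omega2 = 2
      )
    }
  )
  fitAlt <- fitCodonModel(aln, fitNull@tree, pair$alt,
    nStarts = cfg$nStarts,
    seed = gseed + 1L, fixBranchLengths = cfg$fixBranchLengths,
    start = startAlt
  )
  list(null = fitNull, alt = fitAlt)
}

# External backend: write control files + marked tree, run codeml, parse.
.fit_pair_codeml <- function(aln, gtree, cfg, pair, cladeId) {
  if (Sys.which("codeml") == "") stop("codeml binary not found on PATH")
  wd <- tempfile("codeml_")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  seqfile <- file.path(wd, "gene.phy")
  .write_paml_seq(aln, seqfile)
  treefile <- file.path(wd, "gene.trees")
  if (cfg$model == "site") {
    writeLines(ape::write.tree(gtree), treefile)
  } else {
    writeMarkedNewick(gtree, cladeId, scope = cfg$foregroundScope, path = treefile)
  }
  fits <- lapply(c(null = "null", alt = "alt"), function(h) {
    outfile <- file.path(wd, paste0("out_", h, ".txt"))
    ctl <- file.path(wd, paste0(h, ".ctl"))
    codemlControlFile(cfg$model, h, seqfile, treefile, outfile, path = ctl)
    system2("codeml", basename(ctl), stdout = FALSE, stderr = FALSE, wait = TRUE)
    # codeml resolves paths relative to its working directory
    if (!file.exists(outfile)) {
      owd <- setwd(wd)
      on.exit(setwd(owd), add = TRUE)
      system2("codeml", basename(ctl), stdout = FALSE, stderr = FALSE)
      setwd(owd)
    }
    parseCodemlOutput(outfile, bebThreshold = cfg$siteThreshold)
  })
  # adapt parsed numbers into minimal CodonFit objects for classification
  as_fit <- function(parsed, modelId) {
    om <- parsed$omega
    wfg <- if ("foreground" %in% names(om)) om[["foreground"]] else om[[1]]
    wbg <- if ("background" %in% names(om)) om[["background"]] else om[[1]]
    cl <- switch(modelId,
      M0 = siteClassMix("M0", omega = wbg),
      two_ratios = siteClassMix("two_ratios", omega = wbg, omegaFg = wfg),
      siteClassMix("MA",
        p0 = 0.5, p1 = 0.5 - 1e-6, omega0 = min(wbg, 0.999),
        omega2 = max(wfg, 1)
      )
    )
    new("CodonFit",
      modelId = modelId, lnL = parsed$lnL, kappa = 2, pi = rep(1 / 61, 61),
      classes = cl, tree = gtree, convergence = 0L,
      boundary = character(), nStarts = 0L
    )
  }
  list(
    null = as_fit(fits$null, pair$null), alt = as_fit(fits$alt, pair$alt),
    beb = fits$alt$bebSites
  )
}

.write_paml_seq <- function(aln, path) {
  m <- codonMatrix(aln)
  con <- file(path, "wb")
  writeLines(sprintf(" %d %d", nrow(m), ncol(m) * 3L), con)
  for (i in seq_len(nrow(m))) {
    writeLines(rownames(m)[i], con)
    writeLines(paste(m[i, ], collapse = ""), con)
  }
  close(con)
}

#' Run a genome-wide positive selection scan
#'
#' For each foreground clade id (site model: one unlabelled pass), every
#' alignment in the directory is admitted by the filter policy, the
#' species tree is pruned to the alignment's taxa, the clade is marked,
#' the nested model pair is fitted, and a likelihood-ratio test
#' classifies the gene. When `bonferroni = TRUE` and more than one clade
#' is tested, the level is `alpha / n_clades`. Per-gene failures are
#' flagged and never abort the run. Work is distributed over up to
#' `threads` forked workers; per-gene seeds are derived from the global
#' seed and gene id, so results are identical for any thread count.
#'
#' @param cfg A [scanConfig()] object.
#' @return A `selwideResults` list: `outcomes` (list of
#'   [SelectionTest-class]), `flags`, `dnds`, `monophyly` (data frames),
#'   and `config`.
#' @export
runSelectionScan <- function(cfg) {
  stopifnot(inherits(cfg, "selwideConfig"))
  tree <- readNewickTree(cfg$treePath)
  labels <- if (!is.null(cfg$branchLabelPath)) {
    readBranchLabels(cfg$branchLabelPath, tree)
  } else {
    stats::setNames(integer(length(tree$tip.label)), tree$tip.label)
  }
  files <- .list_alignment_files(cfg$alignmentDir)
  if (length(files) == 0L) stop("no alignment files in ", cfg$alignmentDir)

  cladeIds <- if (cfg$model == "site") {
    0L
  } else {
    ids <- sort(unique(labels[labels >= 1L]))
    if (length(ids) == 0L) {
      stop("branch and branch-site models need at least one taxon labelled >= 1")
    }
    ids
  }
  nClades <- length(cladeIds[cladeIds >= 1L])
  alphaUsed <- if (cfg$bonferroni && nClades > 1L) {
    bonferroniAlpha(cfg$alpha, nClades)
  } else {
    cfg$alpha
  }
  pair <- if (cfg$model == "custom") {
    list(null = "custom", alt = "custom", df = cfg$customCtl$df)
  } else {
    .MODEL_PAIRS[[cfg$model]]
  }

  jobs <- expand.grid(
    file = files, clade = cladeIds,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  worker <- function(i) {
    t0 <- proc.time()
    r <- .scan_gene(
      jobs$file[i], cfg, tree, labels, jobs$clade[i],
      alphaUsed, pair
    )
    r$seconds <- unname((proc.time() - t0)["elapsed"])
    r
  }
  results <- if (cfg$threads > 1L) {
    parallel::mclapply(seq_len(nrow(jobs)), worker, mc.cores = cfg$threads)
  } else {
    lapply(seq_len(nrow(jobs)), worker)
  }
  # a killed fork returns a try-error; convert to a flag
  results <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (inherits(r, "try-error") || is.null(r)) {
      gid <- sub("\\.[^.]*$", "", basename(jobs$file[i]))
      list(
        outcome = NULL, flag = .gene_flag(gid, "fit_failure"), dnds = NULL,
        monophyly = NULL, treeText = NULL, seconds = NA_real_
      )
    } else {
      r
    }
  })
  runLog <- data.frame(
    gene_id = sub("\\.[^.]*$", "", basename(jobs$file)),
    clade_id = jobs$clade,
    seconds = round(vapply(results, function(r) {
      if (is.null(r$seconds)) NA_real_ else r$seconds
    }, numeric(1)), 3),
    status = vapply(results, function(r) {
      if (!is.null(r$outcome)) "tested" else r$flag$reason
    }, character(1))
  )
  runLog <- runLog[order(runLog$clade_id, runLog$gene_id), , drop = FALSE]
  rownames(runLog) <- NULL
  trees <- list()
  for (i in seq_along(results)) {
    tt <- results[[i]]$treeText
    if (!is.null(tt)) {
      nm <- paste0(
        sub("\\.[^.]*$", "", basename(jobs$file[i])), "_clade", jobs$clade[i]
      )
      trees[[nm]] <- tt
    }
  }

  collect <- function(field) {
    x <- lapply(results, `[[`, field)
    x <- x[!vapply(x, is.null, logical(1))]
    x
  }
  outcomes <- collect("outcome")
  ord <- order(
    vapply(outcomes, function(o) o@cladeId, integer(1)),
    vapply(outcomes, function(o) o@geneId, character(1))
  )
  outcomes <- outcomes[ord]
  bindOr <- function(field, proto) {
    x <- collect(field)
    if (length(x)) {
      df <- do.call(rbind, x)
      df[do.call(order, df[intersect(c("clade_id", "gene_id"), names(df))]), ,
        drop = FALSE
      ]
    } else {
      proto
    }
  }
  flags <- lapply(seq_along(results), function(i) {
    f <- results[[i]]$flag
    if (!is.null(f)) f$clade_id <- jobs$clade[i]
    f
  })
  flags <- flags[!vapply(flags, is.null, logical(1))]
  flags <- if (length(flags)) {
    df <- do.call(rbind, flags)
    df <- df[order(df$clade_id, df$gene_id), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else {
    data.frame(gene_id = character(), reason = character(), clade_id = integer())
  }
  if (length(outcomes) == 0L && nrow(flags) == nrow(jobs)) {
    warning("no gene was admitted; results are empty")
  }
  message(sprintf(
    "scan: %d files, %d clade(s); %d tested, %d flagged (alpha used = %g)",
    length(files), length(cladeIds), length(outcomes), nrow(flags), alphaUsed
  ))
  structure(
    list(
      outcomes = outcomes,
      flags = flags,
      dnds = bindOr("dnds", data.frame(
        gene_id = character(), clade_id = integer(),
        omega_foreground = numeric(), omega_background = numeric()
      )),
      monophyly = bindOr("monophyly", data.frame(
        gene_id = character(), reason = character()
      )),
      runLog = runLog, trees = trees,
      nInput = length(files), cladeIds = cladeIds, alphaUsed = alphaUsed,
      config = cfg
    ),
    class = "selwideResults"
  )
}

#' Write scan results to TSV files
#'
#' Primary output `positive_selection.tsv`: one line per candidate gene
#' (`gene_id`, `clade_id`, `model_pair`, `lnL_null`, `lnL_alt`,
#' `statistic`, `p_value`, `omega_fg`), followed — for site and
#' branch-site models — by one indented line per positively selected
#' codon (`site <position> <posterior>`, 1-based alignment coordinates).
#' Also written: `all_tests.tsv` (every tested gene), `flags.tsv` (one
#' `gene_id reason` line per skipped/flagged gene), `dnds.tsv` when the
#' scan collected omegas, and `monophyly_flags.tsv` when gene trees were
#' checked. Files are sorted, so outputs are byte-identical for identical
#' results.
#'
#' @param res A `selwideResults` from [runSelectionScan()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeScanResults <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  fmt <- function(x) sprintf("%.6f", x)

  primary <- file.path(dir, "positive_selection.tsv")
  con <- file(primary, "wb")
  writeLines(paste(
    "gene_id", "clade_id", "model_pair", "lnL_null", "lnL_alt",
    "statistic", "p_value", "omega_fg",
    sep = "\t"
  ), con)
  for (o in res$outcomes) {
    if (!o@candidate) next
    writeLines(paste(
      o@geneId, o@cladeId, o@modelPair, fmt(o@lnLNull), fmt(o@lnLAlt),
      fmt(o@statistic), sprintf("%.6g", o@pValue),
      if (is.na(o@omegaFg)) "NA" else fmt(o@omegaFg),
      sep = "\t"
    ), con)
    ps <- o@positiveSites
    if (nrow(ps)) {
      for (i in seq_len(nrow(ps))) {
        writeLines(sprintf("\tsite\t%d\t%.4f", ps$site[i], ps$posterior[i]), con)
      }
    }
  }
  close(con)
  paths <- c(paths, primary)

  allp <- file.path(dir, "all_tests.tsv")
  con <- file(allp, "wb")
  writeLines(paste(
    "gene_id", "clade_id", "model_pair", "lnL_null", "lnL_alt",
    "statistic", "df", "p_value", "alpha_used", "candidate", "omega_fg",
    sep = "\t"
  ), con)
  for (o in res$outcomes) {
    writeLines(paste(
      o@geneId, o@cladeId, o@modelPair, fmt(o@lnLNull), fmt(o@lnLAlt),
      fmt(o@statistic), o@df, sprintf("%.6g", o@pValue),
      sprintf("%.6g", o@alphaUsed), o@candidate,
      if (is.na(o@omegaFg)) "NA" else fmt(o@omegaFg),
      sep = "\t"
    ), con)
  }
  close(con)
  paths <- c(paths, allp)

  flagp <- file.path(dir, "flags.tsv")
  con <- file(flagp, "wb")
  writeLines("gene_id\tclade_id\treason", con)
  if (nrow(res$flags)) {
    writeLines(paste(res$flags$gene_id, res$flags$clade_id, res$flags$reason,
      sep = "\t"
    ), con)
  }
  close(con)
  paths <- c(paths, flagp)

  if (res$config$dndsOut && res$config$model != "site") {
    dp <- file.path(dir, "dnds.tsv")
    con <- file(dp, "wb")
    writeLines("gene_id\tclade_id\tomega_foreground\tomega_background", con)
    if (nrow(res$dnds)) {
      writeLines(paste(res$dnds$gene_id, res$dnds$clade_id,
        fmt(res$dnds$omega_foreground), fmt(res$dnds$omega_background),
        sep = "\t"
      ), con)
    }
    close(con)
    paths <- c(paths, dp)
  } else if (res$config$dndsOut) {
    message("dnds output skipped: site models have no branch-specific omega")
  }

  lp <- file.path(dir, "run_log.tsv")
  con <- file(lp, "wb")
  writeLines("gene_id\tclade_id\tseconds\tstatus", con)
  if (nrow(res$runLog)) {
    writeLines(paste(res$runLog$gene_id, res$runLog$clade_id,
      sprintf("%.3f", res$runLog$seconds), res$runLog$status,
      sep = "\t"
    ), con)
  }
  close(con)
  paths <- c(paths, lp)

  if (length(res$trees)) {
    td <- file.path(dir, "trees")
    dir.create(td, showWarnings = FALSE)
    for (nm in names(res$trees)) {
      con <- file(file.path(td, paste0(nm, ".nwk")), "wb")
      writeLines(res$trees[[nm]], con)
      close(con)
    }
    paths <- c(paths, td)
  }

  if (res$config$geneTrees) {
    mp <- file.path(dir, "monophyly_flags.tsv")
    con <- file(mp, "wb")
    writeLines("gene_id\treason", con)
    if (nrow(res$monophyly)) {
      writeLines(paste(res$monophyly$gene_id, res$monophyly$reason, sep = "\t"), con)
    }
    close(con)
    paths <- c(paths, mp)
  }
  invisible(paths)
}
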