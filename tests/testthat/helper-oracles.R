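# Independent oracles, written from first principles and kept free of the
# package's internal tables and pruning code.

# universal genetic code as a simple lookup
oracle_translate <- local({
  gc <- Biostrings::GENETIC_CODE
  function(codon) unname(gc[codon])
})

oracle_sense_codons <- function() {
  nuc <- c("A", "C", "G", "T")
  all <- as.vector(outer(
    as.vector(outer(nuc, nuc, paste0)), nuc, paste0
  ))
  all <- sort(all)
  all[!all %in% c("TAA", "TAG", "TGA")]
}

# GY94 rate matrix built by looping over codon string pairs (unscaled)
oracle_qraw <- function(kappa, omega, pi) {
  cods <- oracle_sense_codons()
  n <- length(cods)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- strsplit(cods[i], "")[[1]]
      b <- strsplit(cods[j], "")[[1]]
      diff <- which(a != b)
      if (length(diff) != 1L) next
      r <- pi[j]
      pair <- sort(c(a[diff], b[diff]))
      if (identical(pair, c("A", "G")) || identical(pair, c("C", "T"))) {
        r <- r * kappa
      }
      if (oracle_translate(cods[i]) != oracle_translate(cods[j])) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

oracle_q_scaled <- function(kappa, omega, pi) {
  Q <- oracle_qraw(kappa, omega, pi)
  Q / sum(pi * -diag(Q))
}

# mixture-average substitution rate per branch type
oracle_mix_scales <- function(mix, kappa, pi) {
  rate <- function(w) sum(pi * -diag(oracle_qraw(kappa, w, pi)))
  list(
    bg = sum(mix$prop * vapply(mix$omegaBg, rate, numeric(1))),
    fg = sum(mix$prop * vapply(mix$omegaFg, rate, numeric(1)))
  )
}

# Exhaustive-marginalization likelihood for an unrooted 4-taxon tree
# (basal trifurcation: internal nodes 5 = root, 6). States of both
# interior nodes are summed explicitly. Tip states: 1..61 index into
# oracle_sense_codons(), NA = missing.
oracle_loglik_4taxa <- function(tree, tipStates, mix, kappa, pi,
                                marks = NULL) {
  stopifnot(length(tree$tip.label) == 4L, tree$Nnode == 2L)
  if (is.null(marks)) marks <- integer(6)
  scales <- oracle_mix_scales(mix, kappa, pi)
  qcache <- list()
  qfor <- function(w) {
    key <- sprintf("%.17g", w)
    if (is.null(qcache[[key]])) qcache[[key]] <<- oracle_qraw(kappa, w, pi)
    qcache[[key]]
  }
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    fg <- marks[child] > 0
    lapply(seq_len(nrow(mix)), function(k) {
      w <- if (fg) mix$omegaFg[k] else mix$omegaBg[k]
      sc <- if (fg) scales$fg else scales$bg
      as.matrix(Matrix::expm(qfor(w) * tree$edge.length[e] / sc))
    })
  })
  nsites <- ncol(tipStates)
  root <- 5L
  other <- 6L
  total <- 0
  for (s in seq_len(nsites)) {
    sitelik <- 0
    for (k in seq_len(nrow(mix))) {
      tipP <- function(tip, state) {
        e <- which(tree$edge[, 2] == tip)
        P <- Ps[[e]][[k]]
        if (is.na(state)) rep(1, 61) else P[, state]
      }
      # partition tips by parent
      rootTips <- tree$edge[tree$edge[, 1] == root & tree$edge[, 2] <= 4, 2]
      otherTips <- tree$edge[tree$edge[, 1] == other & tree$edge[, 2] <= 4, 2]
      eInt <- which(tree$edge[, 2] == other)
      Pint <- Ps[[eInt]][[k]]
      A <- rep(1, 61)
      for (tp in rootTips) A <- A * tipP(tp, tipStates[tp, s])
      B <- rep(1, 61)
      for (tp in otherTips) B <- B * tipP(tp, tipStates[tp, s])
      lik_k <- 0
      for (x in 1:61) {
        lik_k <- lik_k + pi[x] * A[x] * sum(Pint[x, ] * B)
      }
      sitelik <- sitelik + mix$prop[k] * lik_k
    }
    total <- total + log(sitelik)
  }
  total
}

# all non-trivial bipartitions of an unrooted tree, as canonical strings
# (each side sorted, smaller-side-first), by deleting each internal edge
oracle_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  ntip <- length(tips)
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  out <- character()
  for (e in seq_len(nrow(tree$edge))) {
    side <- sort(below(tree$edge[e, 2]))
    if (length(side) < 2L || length(side) > ntip - 2L) next
    otherSide <- sort(setdiff(tips, side))
    canon <- if (paste(side, collapse = ",") < paste(otherSide, collapse = ",")) {
      paste(paste(side, collapse = ","), paste(otherSide, collapse = ","), sep = "|")
    } else {
      paste(paste(otherSide, collapse = ","), paste(side, collapse = ","), sep = "|")
    }
    out <- c(out, canon)
  }
  sort(unique(out))
}

# restriction of a set of bipartitions to a taxon subset, dropping trivial
# ones — the brute-force pruning oracle
oracle_restrict_bipartitions <- function(bips, taxa) {
  out <- character()
  for (b in bips) {
    sides <- strsplit(b, "|", fixed = TRUE)[[1]]
    s1 <- intersect(strsplit(sides[1], ",")[[1]], taxa)
    s2 <- intersect(strsplit(sides[2], ",")[[1]], taxa)
    if (length(s1) < 2L || length(s2) < 2L) next
    s1 <- sort(s1)
    s2 <- sort(s2)
    canon <- if (paste(s1, collapse = ",") < paste(s2, collapse = ",")) {
      paste(paste(s1, collapse = ","), paste(s2, collapse = ","), sep = "|")
    } else {
      paste(paste(s2, collapse = ","), paste(s1, collapse = ","), sep = "|")
    }
    out <- c(out, canon)
  }
  sort(unique(out))
}

# leaf-to-leaf path length by walking parent chains to the common ancestor
oracle_path_length <- function(tree, a, b) {
  ntip <- length(tree$tip.label)
  up <- function(node) {
    path <- numeric()
    nodes <- node
    while (TRUE) {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      path <- c(path, tree$edge.length[e])
      node <- tree$edge[e, 1]
      nodes <- c(nodes, node)
    }
    list(nodes = nodes, cum = c(0, cumsum(path)))
  }
  pa <- up(match(a, tree$tip.label))
  pb <- up(match(b, tree$tip.label))
  common <- intersect(pa$nodes, pb$nodes)[1]
  pa$cum[match(common, pa$nodes)] + pb$cum[match(common, pb$nodes)]
}

# convenience: random taxon-labelled fixture alignment writer
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  close(con)
  path
}

# fixed 6-taxon study tree used across tests: a 2-species foreground clade
# and 4 background taxa
study_tree <- function() {
  ape::read.tree(
    text = "((F1:0.15,F2:0.15):0.1,((B1:0.2,B2:0.2):0.1,(B3:0.25,B4:0.25):0.1):0.05);"
  )
}

study_labels <- function(tree = study_tree()) {
  stats::setNames(
    ifelse(grepl("^F", tree$tip.label), 1L, 0L),
    tree$tip.label
  )
}
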