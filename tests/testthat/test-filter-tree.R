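test_that("admission applies the foreground/background count thresholds", {
  aln <- CodonAlignment("g", c(
    F1 = "ATGAAA", F2 = "ATGAAG", F3 = "ATGAAC", F4 = "ATGAAT",
    B1 = "ATGGAA", B2 = "ATGGAG", B3 = "ATGGAC"
  ))
  labels <- c(F1 = 1L, F2 = 1L, F3 = 1L, F4 = 1L, B1 = 0L, B2 = 0L, B3 = 0L, B4 = 0L)

  # the defaults admit everything duplicate-free
  expect_true(admitGene(aln, labels, 1L)$admitted)
  # 4 foreground / 3 background passes the case-study thresholds exactly
  expect_true(admitGene(aln, labels, 1L, minForeground = 4, minBackground = 3)$admitted)

  sub <- CodonAlignment("g", codonMatrix(aln)[c("F1", "F2", "F3", "F4", "B1", "B2"), ])
  r <- admitGene(sub, labels, 1L, minForeground = 4, minBackground = 3)
  expect_false(r$admitted)
  expect_identical(r$flag$reason, "below_min_background")

  r <- admitGene(sub, labels, 1L, minForeground = 5, minBackground = 0)
  expect_identical(r$flag$reason, "below_min_foreground")
})

test_that("pruning restricts the topology and sums through removed nodes", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  p <- pruneToAlignment(tr, c("A", "B", "C"))
  expect_setequal(p$tip.label, c("A", "B", "C"))
  # only trivial bipartitions remain on 3 taxa
  expect_identical(oracle_bipartitions(p), character(0))

  tr2 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  p2 <- pruneToAlignment(tr2, c("A", "C"))
  expect_equal(oracle_path_length(p2, "A", "C"), 4)

  # identity restriction
  pfull <- pruneToAlignment(tr, tr$tip.label)
  expect_identical(oracle_bipartitions(pfull), oracle_bipartitions(tr))

  expect_error(pruneToAlignment(tr, c("A", "X")), "not in tree")
  expect_error(pruneToAlignment(tr, "A"), "at least 2")
})

test_that("pruning is idempotent and preserves leaf-pair distances", {
  set.seed(71)
  for (rep in 1:5) {
    tr <- ape::rtree(8)
    taxa <- sample(tr$tip.label, sample(3:7, 1))
    p1 <- pruneToAlignment(tr, taxa)
    p2 <- pruneToAlignment(p1, taxa)
    expect_identical(oracle_bipartitions(p2), oracle_bipartitions(p1))
    pairs <- utils::combn(taxa, 2)
    for (j in seq_len(ncol(pairs))) {
      expect_equal(
        oracle_path_length(p1, pairs[1, j], pairs[2, j]),
        oracle_path_length(tr, pairs[1, j], pairs[2, j]),
        tolerance = 1e-9
      )
    }
  }
})

test_that("foreground marking covers the clade and detects non-monophyly", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  res <- markForeground(tr, c(A = 1L, B = 1L, C = 0L, D = 0L), 1L)
  expect_true(res$monophyletic)
  marks <- res$tree$node.mark
  ntip <- length(res$tree$tip.label)
  markedTips <- res$tree$tip.label[which(marks[seq_len(ntip)] == 1L)]
  expect_setequal(markedTips, c("A", "B"))
  # clade scope: two terminal branches plus the stem
  expect_identical(sum(marks == 1L), 3L)

  stem <- markForeground(tr, c(A = 1L, B = 1L, C = 0L, D = 0L), 1L, scope = "stem")
  expect_identical(sum(stem$tree$node.mark == 1L), 1L)

  bad <- markForeground(
    ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);"),
    c(A = 1L, B = 1L, C = 0L, D = 0L), 1L
  )
  expect_false(bad$monophyletic)
  expect_identical(bad$flag$reason, "foreground_not_monophyletic_species_tree")

  single <- markForeground(tr, c(A = 1L, B = 0L, C = 0L, D = 0L), 1L)
  expect_true(single$monophyletic)
  expect_identical(which(single$tree$node.mark == 1L), match("A", single$tree$tip.label))
})

test_that("marking verdict agrees with the unrooted monophyly check", {
  set.seed(13)
  for (rep in 1:20) {
    tr <- ape::rtree(7)
    fg <- sample(tr$tip.label, sample(2:5, 1))
    labels <- stats::setNames(
      as.integer(tr$tip.label %in% fg), tr$tip.label
    )
    expect_identical(
      markForeground(tr, labels, 1L)$monophyletic,
      checkMonophyly(tr, fg)
    )
  }
})

test_that("complete-ortholog selection requires exact taxon-set equality", {
  mk <- function(id, taxa) {
    CodonAlignment(id, stats::setNames(rep("ATG", length(taxa)), taxa))
  }
  alns <- list(
    mk("g1", c("A", "B", "C")),
    mk("g2", c("A", "B")),
    mk("g3", c("C", "B", "A")),
    mk("g4", c("A", "B", "C", "D"))
  )
  expect_setequal(selectCompleteOrthologs(alns, c("A", "B", "C")), c("g1", "g3"))
  expect_identical(selectCompleteOrthologs(list(), c("A", "B")), character(0))
})

test_that("NJ gene trees recover a planted AB|CD split deterministically", {
  base <- paste(rep("ATG", 40), collapse = "")
  a <- b <- c_ <- d <- base
  # 10 private AB substitutions, 10 private CD substitutions (synonymous-safe
  # not required here; p-distance only)
  substr(a, 1, 30) <- paste(rep("ACA", 10), collapse = "")
  substr(b, 1, 30) <- paste(rep("ACA", 10), collapse = "")
  substr(c_, 61, 90) <- paste(rep("ACG", 10), collapse = "")
  substr(d, 61, 90) <- paste(rep("ACG", 10), collapse = "")
  aln <- CodonAlignment("g", c(A = a, B = b, C = c_, D = d))
  tr1 <- buildGeneTree(aln)
  expect_identical(oracle_bipartitions(tr1), "A,B|C,D")
  expect_true(checkMonophyly(tr1, c("A", "B")))
  expect_false(checkMonophyly(tr1, c("A", "C")))
  expect_true(checkMonophyly(tr1, c("A", "B", "C", "D")))
  expect_true(checkMonophyly(tr1, "A"))
  # determinism
  tr2 <- buildGeneTree(aln)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))

  expect_error(buildGeneTree(CodonAlignment("g", c(A = "ATG", B = "ATG"))), "3 taxa")
  # identical sequences give a valid zero-length tree
  same <- CodonAlignment("g", c(A = base, B = base, C = base, D = base))
  tr0 <- buildGeneTree(same)
  expect_true(all(tr0$edge.length <= 1e-12))
})

test_that("pairwise-deletion distances ignore gapped sites", {
  aln <- CodonAlignment("g", c(
    A = "ATGATGATG",
    B = "ATGATGCTG",
    C = "---ATGCTG",
    D = "ATGATGAT-"
  ))
  # A vs B differ at 1 of 9 comparable sites
  tr <- buildGeneTree(aln)
  expect_s3_class(tr, "phylo")
})
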