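ctl_kv <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  kv <- strsplit(lines, "\\s*=\\s*")
  stats::setNames(
    vapply(kv, `[`, character(1), 2),
    vapply(kv, `[`, character(1), 1)
  )
}

test_that("control files carry the documented settings for all hypotheses", {
  expected <- list(
    list("branch", "null", c(model = "0", NSsites = "0")),
    list("branch", "alt", c(model = "2", NSsites = "0")),
    list("site", "null", c(model = "0", NSsites = "1")),
    list("site", "alt", c(model = "0", NSsites = "2")),
    list("branch-site", "null", c(model = "2", NSsites = "2", fix_omega = "1", omega = "1")),
    list("branch-site", "alt", c(model = "2", NSsites = "2", fix_omega = "0"))
  )
  for (e in expected) {
    kv <- ctl_kv(codemlControlFile(e[[1]], e[[2]], "s.phy", "t.nwk", "o.txt"))
    for (key in names(e[[3]])) {
      expect_identical(kv[[key]], e[[3]][[key]])
    }
    # constants present in every file
    expect_identical(kv[["seqtype"]], "1")
    expect_identical(kv[["CodonFreq"]], "2")
    expect_identical(kv[["cleandata"]], "0")
    expect_identical(kv[["fix_kappa"]], "0")
    expect_identical(kv[["seqfile"]], "s.phy")
  }
})

test_that("null and alt control files differ only in the documented keys", {
  for (model in c("branch", "site", "branch-site")) {
    kvN <- ctl_kv(codemlControlFile(model, "null", "s", "t", "o"))
    kvA <- ctl_kv(codemlControlFile(model, "alt", "s", "t", "o"))
    expect_identical(names(kvN), names(kvA))
    changed <- names(kvN)[kvN != kvA]
    allowed <- switch(model,
      branch = "model",
      site = "NSsites",
      `branch-site` = c("fix_omega", "omega")
    )
    expect_true(all(changed %in% allowed))
  }
})

test_that("control files are byte-stable and model ids map onto hypotheses", {
  a <- codemlControlFile("branch-site", "null", "s", "t", "o")
  b <- codemlControlFile("branch-site", "null", "s", "t", "o")
  expect_identical(a, b)
  expect_false(grepl("\r", a))
  # model-id aliases
  expect_identical(codemlControlFile("MA_null", seqfile = "s", treefile = "t", outfile = "o"), a)
  expect_identical(
    codemlControlFile("M0", seqfile = "s", treefile = "t", outfile = "o"),
    codemlControlFile("branch", "null", "s", "t", "o")
  )
  expect_error(codemlControlFile("M9", "null", "s", "t", "o"), "unknown model")
  f <- withr::local_tempfile()
  codemlControlFile("site", "alt", "s", "t", "o", path = f)
  expect_identical(readChar(f, file.size(f)), codemlControlFile("site", "alt", "s", "t", "o"))
})

test_that("marked Newick output tags the clade or stem as PAML expects", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  mk <- markForeground(tr, c(A = 1L, B = 1L, C = 0L, D = 0L), 1L)$tree
  clade <- writeMarkedNewick(mk, 1L, scope = "clade")
  expect_match(clade, "\\(A,B\\) ?\\$1", fixed = FALSE)
  stemTree <- markForeground(tr, c(A = 1L, B = 1L, C = 0L, D = 0L), 1L, scope = "stem")$tree
  stem <- writeMarkedNewick(stemTree, 1L, scope = "stem")
  expect_match(stem, "\\(A,B\\) ?#1", fixed = FALSE)
  # single-leaf foreground always gets #1 on its terminal branch
  single <- markForeground(tr, c(A = 1L, B = 0L, C = 0L, D = 0L), 1L)$tree
  expect_match(writeMarkedNewick(single, 1L), "A ?#1", fixed = FALSE)
  expect_error(writeMarkedNewick(tr, 1L), "no branch marked")
})

test_that("codeml output parsing extracts lnL, omegas and BEB sites", {
  fx <- function(name) system.file("extdata", name, package = "selwide")

  alt <- parseCodemlOutput(fx("codeml_branch_site_alt_synthetic.txt"))
  expect_equal(alt$lnL, -3735.071234)
  expect_equal(unname(alt$omega["background"]), 0.0835)
  expect_equal(unname(alt$omega["foreground"]), 5.45697)
  # 0.952 and 0.991 retained; 0.930 retained; 0.900 is NOT > 0.9; 0.850 out
  expect_identical(alt$bebSites$site, c(12L, 17L, 44L))
  expect_identical(alt$bebSites$aminoAcid, c("K", "A", "T"))
  expect_equal(alt$bebSites$posterior, c(0.952, 0.991, 0.930))

  null <- parseCodemlOutput(fx("codeml_branch_site_null_synthetic.txt"))
  expect_equal(null$lnL, -3751.923456)
  expect_identical(nrow(null$bebSites), 0L)

  branch <- parseCodemlOutput(fx("codeml_branch_alt_synthetic.txt"))
  expect_equal(unname(branch$omega), c(0.28153, 4.9546))

  m0 <- parseCodemlOutput(fx("codeml_m0_synthetic.txt"))
  expect_equal(m0$lnL, -4056.599481)
  expect_equal(unname(m0$omega["omega"]), 0.2919)

  m2a <- parseCodemlOutput(fx("codeml_m2a_synthetic.txt"))
  expect_identical(m2a$bebSites$site, c(7L, 33L))

  expect_error(parseCodemlOutput(c("no likelihood here")), "lnL")
})
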