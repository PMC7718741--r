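# selwide

Genome-wide scans for positive selection in protein-coding genes, using
nested codon substitution models on a species tree.

## What it does, and for whom

Comparative genomicists routinely ask whether particular lineages — a
domesticated yeast clade, a host-switched parasite branch — show an
excess of amino-acid substitutions in some genes. The standard measure
is ω = dN/dS, the ratio of nonsynonymous to synonymous substitution
rates: ω < 1 indicates purifying selection, ω = 1 neutrality, ω > 1
positive selection. Testing this gene by gene over thousands of ortholog
groups is mechanical but fiddly: alignments have different taxon subsets,
the species tree must be pruned per gene, foreground branches must be
marked, two nested models fitted per gene, and likelihood-ratio tests
collected and corrected.

`selwide` automates the whole workflow:

* **filters** ortholog alignments (one sequence per taxon; optional
  minimum numbers of foreground/background taxa, both default 0);
* **prunes** the species topology to each alignment's taxa and **marks**
  the foreground clade(s) from a simple `taxon integer` label file
  (several integers ≥ 1 = several clades, scanned one after another);
* **fits** the three classical nested pairs of Goldman–Yang codon
  models — branch (M0 vs two-ratios), site (M1a vs M2a) and branch-site
  (model A null vs model A) — with a built-in maximum-likelihood engine
  (Felsenstein pruning, F3x4 frequencies, compiled inner loop);
* **tests** each gene by an LRT (χ² with 1, 2, 1 df respectively), with
  optional Bonferroni correction α/n over the tested clades;
* **classifies** candidates (p < α and, for branch-like models,
  foreground ω̂ > 1) and reports positively selected codon positions
  (posterior > 0.9, only when the LRT is significant);
* optionally **drives codeml** instead of the internal engine: it writes
  PAML control files and parses `codeml` main output including BEB site
  tables.

A codon-alignment **simulator** for all supported models (with per-site
truth labels) doubles as the test-fixture generator and as a power
calculator for study design.

## Worked example

Simulate a small "genome" of 8 ortholog groups on a 6-taxon tree — six
neutral genes and two with foreground ω = 5 on the (F1,F2) clade — and
scan it with the branch-site test:

```r
library(selwide)
library(ape)

tree <- read.tree(text =
  "((F1:0.15,F2:0.15):0.1,((B1:0.2,B2:0.2):0.1,(B3:0.25,B4:0.25):0.1):0.05);")
labels <- setNames(ifelse(grepl("^F", tree$tip.label), 1L, 0L), tree$tip.label)
mtree  <- markForeground(tree, labels, 1L)$tree

dir.create(d <- tempfile())
mixes <- c(rep(list(siteClassMix("M0", omega = 0.2)), 6),
           rep(list(siteClassMix("MA", p0 = .4, p1 = .3, omega0 = .1, omega2 = 5)), 2))
for (i in seq_along(mixes)) {
  aln <- simulateCodonAlignment(mtree, mixes[[i]], kappa = 2, nSites = 300, seed = i)
  m <- codonMatrix(aln)
  writeLines(paste0(">", rownames(m), "\n", apply(m, 1, paste, collapse = "")),
             file.path(d, sprintf("gene%d.fa", i)))
}
writeNewickTree(tree, file.path(d, "species.nwk"))
writeLines(c("F1 1", "F2 1"), file.path(d, "branches.txt"))

cfg <- scanConfig(d, file.path(d, "species.nwk"), file.path(d, "branches.txt"),
                  model = "branch-site", seed = 1, nStarts = 1)
res <- runSelectionScan(cfg)
res$outcomes[[7]]
```

```
SelectionTest gene7 (clade 1, MA_null_vs_MA)
  2*dlnL = 17.1069  df = 1  p = 3.533e-05  candidate: TRUE
  positively selected sites: 6(0.986) 23(0.913) 25(0.953) 95(0.925) 132(0.955) 162(0.957) 168(0.966) 232(0.989) 248(0.929) 249(0.994) 263(0.963) 265(0.945) 275(0.981)
```

The two planted genes (7 and 8) come out as the only candidates: gene
line, LRT statistic, χ²₁ p-value, and the codon positions whose
positive-class posterior exceeds 0.9. `writeScanResults(res, "out/")`
writes the same information as TSV (`positive_selection.tsv`,
`all_tests.tsv`, `flags.tsv`, plus `dnds.tsv` / `monophyly_flags.tsv`
when requested).

The same scan runs from a shell:

```sh
exec/selwide scan --cds-dir alns/ --tree species.nwk --branches branches.txt \
    --model branch-site -p 4 --out results/
exec/selwide simulate --tree species.nwk --model MA --omega2 5 --out sim1
```

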