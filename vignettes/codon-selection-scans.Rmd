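---
title: "Genome-wide positive selection scans with codon models"
author: "selwide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide positive selection scans with codon models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selwide)
library(ape)
```

## The problem

A recurring task in comparative genomics is to screen thousands of
ortholog groups for genes under positive selection on a clade of
interest: did a set of lineages (say, a pair of *Saccharomyces* species)
accumulate amino-acid replacements faster than neutrality allows, and in
which genes and codons? The standard machinery is the ratio
$\omega = d_N/d_S$ of nonsynonymous to synonymous substitution rates in
protein-coding sequence: under neutrality $\omega = 1$, purifying
selection drives it below one, and positive selection above one.

`selwide` runs this screen end to end. Given a directory of codon-aligned
ortholog groups (FASTA, at most one sequence per taxon), a species tree
and a branch-label file naming one or more foreground clades, it admits
genes through configurable filters, prunes the species topology to the
taxa of each alignment, marks the foreground branches, fits nested codon
models, and performs likelihood-ratio tests (LRTs) with optional
Bonferroni correction, reporting candidate genes and, for site-aware
models, the codon positions involved. Model fitting uses a built-in
maximum-likelihood engine; a `codeml` interoperability layer generates
PAML control files and parses `codeml` main output, so the same scan can
drive the external program where that is preferred.

## The models

All models are Goldman–Yang (GY94) codon models on the 61 sense codons of
the universal code. The instantaneous rate from codon $i$ to $j$ is 0 if
they differ at more than one position, and otherwise
$$q_{ij} = \pi_j \cdot \kappa^{\mathbb{1}[\text{transition}]} \cdot
\omega^{\mathbb{1}[\text{nonsynonymous}]},$$
with equilibrium frequencies $\pi$ (F3x4 by default: positional
nucleotide frequencies multiplied and renormalized over sense codons,
floored at $10^{-8}$), transition/transversion ratio $\kappa$, and
selection parameter $\omega$. Three nested hypothesis pairs are built in:

| test        | null (constraint)           | alternative            | df |
|-------------|-----------------------------|------------------------|----|
| branch      | M0, one $\omega$            | two-ratios ($\omega_{fg}$ free) | 1 |
| site        | M1a ($\omega_0 < 1$, $\omega_1 = 1$) | M2a (adds $\omega_2 \ge 1$) | 2 |
| branch-site | model A with $\omega_2 = 1$ | model A                | 1 |

Model A uses four site classes $(p_0;\,\omega_0,\omega_0)$,
$(p_1;\,1,1)$, $(p_{2a};\,\omega_0,\omega_2)$, $(p_{2b};\,1,\omega_2)$
with $p_{2a} = (1 - p_0 - p_1)\,p_0/(p_0+p_1)$ and
$p_{2b} = (1 - p_0 - p_1)\,p_1/(p_0+p_1)$: the "2" classes switch to
$\omega_2$ on the foreground branches only.

A modeling point that matters in practice: all site classes share a
single rate scale per branch type, the mixture-weighted mean substitution
rate. Branch lengths therefore count expected substitutions per codon
averaged over classes, and — crucially — the synonymous rate is the same
for every class. Normalizing each class's matrix separately would let a
high-$\omega$ class trade nonsynonymous gains for synonymous losses,
discarding most of the rate signal the branch-site test relies on; the
shared scale is also what `codeml` does, keeping the internal engine and
the external backend comparable.

## Likelihood, fitting, and posteriors

The log-likelihood is computed by Felsenstein pruning over the site-class
mixture,
$\ell = \sum_s \log \sum_k p_k L(x_s \mid k)$, with transition matrices
$P(t) = e^{Qt}$ obtained by symmetric eigendecomposition of the
reversible $Q$ (via the $\pi^{1/2}$ similarity transform), per-node
rescaling against underflow, all-ones partial vectors for codons
containing `-` or `N` (no column deletion, preserving site numbering —
the analogue of `cleandata = 0`), and root weighting by $\pi$. Site
patterns are compressed before pruning; the inner loop is compiled
(RcppArmadillo) with the pure-R recursion retained and cross-checked in
the tests.

Fitting maximizes $\ell$ over $\kappa$, the model's free $\omega$ and
proportion parameters, and (by default) all branch lengths, with
L-BFGS-B on transformed coordinates: $\log \kappa$ in
$[\log 0.01, \log 100]$, $\log \omega$ with $\omega_0 \in [10^{-4}, 1)$
and $\omega_2 \in [1, 999]$, stick-breaking logits for proportions, and
$\log$ branch lengths in $[10^{-8}, 50]$. Multi-start is supported
(`nStarts` seeded jitters around a deterministic heuristic start); the
genome-scale pipeline defaults to a single heuristic start per fit, with
the alternative model started from the null's solution — this keeps the
nesting inequality $\ell_{alt} \ge \ell_{null}$ reliable at far lower
cost than cold multi-starts, and is also why negative LRT statistics
(possible from optimizer jitter at tolerance $\sim 10^{-5}$) are clamped
to zero. Branch lengths are re-estimated under every model by default;
`fixBranchLengths = TRUE` reuses a one-ratio (M0) estimate, the common
speed-up in genome scans. Convergence to a box boundary (e.g.
$\hat\omega_2 \to 1$, $\hat p_2 \to 0$) is reported in the fit object.

Per-site posteriors are naive empirical Bayes (NEB):
$P(k \mid x_s) \propto \hat p_k L(x_s \mid k)$ at the MLEs, with
"positively selected" mass being the posterior of the classes whose
foreground $\omega$ may exceed one (class 2 of M2a; 2a + 2b of model A).
The hierarchical-prior BEB calculation is deliberately not implemented
internally: it is a substantial, separate piece of machinery, and when
the scan drives `codeml` its BEB table is parsed and used instead. The
0.9 reporting threshold (strictly greater) applies to whichever source
is active; this NEB/BEB distinction is the main caveat when comparing
internal-engine site lists to `codeml` ones.

## Testing and classification rules

For each gene and each foreground clade id ($\ge 1$) in the label file,
the LRT statistic is $\max(0,\, 2(\ell_{alt} - \ell_{null}))$ against
$\chi^2$ with the pair's df. The branch-site null is tested against
$\chi^2_1$ rather than the $\tfrac12(\chi^2_0 + \chi^2_1)$ mixture; this
is the conservative direction. A gene is a candidate iff $p < \alpha$
and, for branch and branch-site models, the foreground $\hat\omega$
exceeds one. Positively selected sites are reported only when the LRT is
significant. With several foreground clades and `bonferroni = TRUE`, the
level becomes $\alpha / n_{\text{clades}}$ — the correction counts
tested clades, not genes, matching a correction applied "when multiple
branches are tested".

## Filters, pruning, and gene trees

FASTA record names are resolved to tree taxa by requiring the taxon
label to occur as a substring of the record name, uniquely; zero or
multiple matches, or two records resolving to one taxon, flag the gene
(reading never aborts a run). This substring rule is one concrete choice
of "common denominator" naming and is the package's convention.
Admission requires at least `minForeground` foreground and
`minBackground` background taxa (both default 0). The species tree is
then pruned to the alignment's taxa: the result's bipartitions are
exactly the restrictions of the input's, degree-2 nodes are collapsed
with lengths summed, so leaf-to-leaf distances are preserved.

Foreground marking defaults to the whole clade (stem plus all internal
and terminal branches); `foregroundScope = "stem"` marks the stem only.
The choice is exposed because branch-label conventions differ between
studies; clade scope matches labeling taxa clade-wise. If the foreground
taxa present after pruning are not monophyletic in the species tree the
gene is skipped with a flag rather than an error — genome-wide runs must
not abort. Optionally (`geneTrees = TRUE`) a neighbor-joining gene tree
is built from pairwise-deletion nucleotide p-distances and genes where
the foreground is not monophyletic in the gene tree are flagged
(informationally; they are still tested against the species tree).
Monophyly is always judged on unrooted bipartitions, avoiding rooting
artifacts. `selectCompleteOrthologs()` returns the genes whose taxon set
equals the species set exactly (strict equality, not superset — the
stricter reading of "containing sequences for all species").

## The simulator

`simulateCodonAlignment()` is the generative twin of the engine: each
site draws a latent class, the root codon is drawn from $\pi$, and
states evolve by sampling from the same $P(t)$ matrices the likelihood
uses (per-branch endpoint sampling is exact under the model; no
event-level simulation is needed because only tip states matter). It
returns the true class per site, so tests can score posteriors against
truth. It emulates branch-, site- and branch-site-heterogeneous
$\omega$, but not indels, rate variation beyond the $\omega$ classes,
non-stationarity, or alignment error — so green tests certify the
inferential machinery, not robustness to real-data artifacts.

## Validation, problem sizes, and determinism

The test suite validates the engine against independent oracles: the
likelihood against exhaustive marginalization over interior-node states
(random 4-taxon trees, mixed models, random marks; agreement to
$10^{-8}$), the rate matrix against an independently constructed GY94
matrix, pruning against brute-force bipartition restriction over all
leaf subsets of 50 random 8-leaf trees, and $\chi^2$ tails against
numerical integration. Statistical behavior is checked by seeded
simulation at desk scale: 10 M0 recoveries (500 codons, 6 taxa,
$\omega = 0.3$), branch-test calibration over 80 null replicates of 300
codons (rejection at $\alpha = 0.05$ expected in $[0.01, 0.10]$) plus 15
power replicates at $\omega_{fg} = 5$, and a 30-gene branch-site
benchmark (6 planted positives at $\omega_2 = 5$, 24 nulls) in which the
scan is expected to recover at least 4 positives with at most 2 false
positives and to produce byte-identical result files for 1 and 4 threads
(the per-gene timing log is the one deliberately run-specific output).
These sizes were chosen as the smallest at which the statistical
expectations are sharp; they are stated here so that the claims are
reproducible as written. `scripts/acceptance.R` re-runs the same
computations (with a reduced calibration arm) and writes the numbers as
JSON.

Determinism is by construction: per-gene seeds are derived from the
global seed and the gene id, outputs are sorted, and files are written
with LF endings, so a scan's results are identical for any thread count.

## Known limitations

* NEB, not BEB, site posteriors from the internal engine (see above).
* Universal genetic code only (the code table is a single point of
  extension); codons are the unit — alignments must be in frame.
* No paralogy handling: files with two sequences for one taxon are
  flagged, not resolved; no gene-tree/species-tree reconciliation.
* The $\chi^2_1$ reference for the branch-site test is conservative near
  the boundary; borderline p-values just under $\alpha$ should be read
  accordingly.
* F3x4 frequencies are estimated once per gene and held fixed during
  optimization, as is standard.
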