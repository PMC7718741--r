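CODONML (in paml version 4.9, March 2015)  gene.phy
Model 2: several dN/dS ratios for branches for branches,  NSsites 2

Synthetic example of a PAML 4.9 main result file, constructed to exercise
the output parser (branch-site model A, alternative hypothesis).

ns =   6  ls = 300

lnL(ntime:  9  np: 14):  -3735.071234      +0.000000

kappa (ts/tv) =  2.01234

MLEs of dN/dS (w) for site classes (K=4)

site class             0        1       2a       2b
proportion       0.52987  0.26875  0.13361  0.06777
background w     0.08350  1.00000  0.08350  1.00000
foreground w     0.08350  1.00000  5.45697  5.45697

Bayes Empirical Bayes (BEB) analysis (Yang, Wong & Nielsen 2005)
Positive sites for foreground lineages Prob(w>1):
    12 K 0.952*
    17 A 0.991**
    44 T 0.930
    61 S 0.900
   102 R 0.850

The grid (opt. 1): dimensions used in the BEB calculation omitted here.
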