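CODONML (in paml version 4.9, March 2015)  gene.phy
Model 2: several dN/dS ratios for branches for branches,  NSsites 2

Synthetic example of a PAML 4.9 main result file, constructed to exercise
the output parser (branch-site model A, null hypothesis: w2 fixed at 1).

ns =   6  ls = 300

lnL(ntime:  9  np: 13):  -3751.923456      +0.000000

kappa (ts/tv) =  1.98765

MLEs of dN/dS (w) for site classes (K=4)

site class             0        1       2a       2b
proportion       0.56561  0.19145  0.18151  0.06144
background w     0.11724  1.00000  0.11724  1.00000
foreground w     0.11724  1.00000  1.00000  1.00000
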