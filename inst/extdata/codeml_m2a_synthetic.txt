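CODONML (in paml version 4.9, March 2015)  gene.phy
Model 0: one dN/dS ratio, NSsites 2 (PositiveSelection)

Synthetic example of a PAML 4.9 main result file, constructed to exercise
the output parser (site model M2a).

ns =   6  ls = 300

lnL(ntime:  9  np: 14):  -3801.234567  +0.000000

kappa (ts/tv) =  2.11111

dN/dS (w) for site classes (K=3)

p:   0.81000  0.12000  0.07000
w:   0.09000  1.00000  3.41000

Bayes Empirical Bayes (BEB) analysis (Yang, Wong & Nielsen 2005)
Positively selected sites (*: P>95%; **: P>99%)

     7 L 0.977*
    33 G 0.912
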