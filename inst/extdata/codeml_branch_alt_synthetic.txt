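CODONML (in paml version 4.9, March 2015)  gene.phy
Model 2: several dN/dS ratios for branches

Synthetic example of a PAML 4.9 main result file, constructed to exercise
the output parser (two-ratios branch model).

ns =   6  ls = 300

lnL(ntime:  9  np: 12):  -4055.636012 +0.000000

kappa (ts/tv) =  2.04321

w (dN/dS) for branches:  0.28153 4.95460

dN & dS for each branch omitted in this synthetic fixture.
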