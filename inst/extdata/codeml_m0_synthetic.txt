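CODONML (in paml version 4.9, March 2015)  gene.phy
Model 0: one dN/dS ratio

Synthetic example of a PAML 4.9 main result file, constructed to exercise
the output parser (one-ratio M0 fit).

ns =   6  ls = 300

lnL(ntime:  9  np: 11):  -4056.599481  +0.000000

kappa (ts/tv) =  1.97650

omega (dN/dS) =  0.29190
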