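# The nine essential amino acids (BiGG-style base ids).
his_L
ile_L
leu_L
lys_L
met_L
phe_L
thr_L
trp_L
val_L
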