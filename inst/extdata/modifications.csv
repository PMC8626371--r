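name,formula
acetyl,C2H2O
carbamidomethyl,C2H3NO
phospho,HO3P
methyl,CH2
dimethyl,C2H4
trimethyl,C3H6
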