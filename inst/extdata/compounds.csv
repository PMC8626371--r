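name,formula
acetyl-coa,C23H38N7O17P3S
glucose,C6H12O6
nad,C21H27N7O14P2
atp,C10H16N5O13P3
glutamate,C5H9NO4
citrate,C6H8O7
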