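sample	time	No label	2C13	4C13
t0	0	84.1	15.9	0.0
t24	24	28.3	46.2	25.6
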