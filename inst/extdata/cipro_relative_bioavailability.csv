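brand,fr_pct
A,93.24
B,98.05
C,104.01
D,101.58
E,108.01
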