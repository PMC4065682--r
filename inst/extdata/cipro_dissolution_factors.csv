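product_id,f2,f1
A,44.63,13.55
B,66.95,3.56
C,58.17,0.78
D,48.40,3.73
E,58.43,5.90
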