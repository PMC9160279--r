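element,percent
C,45.19
N,3.579
H,7.299
S,0.94
O,42.992
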