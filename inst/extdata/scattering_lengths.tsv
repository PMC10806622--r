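label	b_fm
H	-3.739
D	6.671
C	6.646
N	9.36
O	5.803
Cl	9.577
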