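fragment
[H]
C
CC
CCC
C(C)C
O
OC
OCC
N
CO
F
Cl
Br
C#N
C(F)(F)F
C(=O)OC
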