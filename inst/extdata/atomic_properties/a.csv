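element,value
H,0.123
B,0.17
C,0.107
N,-0.6
O,-0.275
F,0.402
Si,0.829
P,0.86
S,0.6
Cl,0.663
Br,0.847
I,1.05
Fe,-0.08
Co,-0.08
Ni,-0.08
Cu,-0.08
Zn,-0.08
Ru,-0.08
Rh,-0.08
Pd,-0.08
Os,-0.08
Ir,-0.08
Pt,-0.08
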