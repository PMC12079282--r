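element,value
H,0
B,0
C,0
N,11.68
O,15.23
F,0
Si,0
P,13.59
S,25.3
Cl,0
Br,0
I,0
Fe,0
Co,0
Ni,0
Cu,0
Zn,0
Ru,0
Rh,0
Pd,0
Os,0
Ir,0
Pt,0
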