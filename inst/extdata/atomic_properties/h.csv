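element,value
H,6.43
B,4.01
C,5
N,7.23
O,6.08
F,7.01
Si,3.38
P,4.88
S,4.14
Cl,4.68
Br,4.22
I,3.69
Fe,3.81
Co,3.6
Ni,3.25
Cu,3.25
Zn,4.94
Ru,3
Rh,3.16
Pd,3.89
Os,3.8
Ir,3.8
Pt,3.5
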