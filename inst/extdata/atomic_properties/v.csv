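element,value
H,7.238
B,29.648
C,20.58
N,15.599
O,14.71
F,13.306
Si,38.792
P,24.429
S,24.429
Cl,22.449
Br,26.522
I,32.515
Fe,35.561
Co,33.51
Ni,32.025
Cu,31.54
Zn,34.015
Ru,37.153
Rh,31.059
Pd,36.087
Os,42.213
Ir,40.479
Pt,40.479
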