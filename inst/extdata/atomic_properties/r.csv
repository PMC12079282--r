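element,value
H,1.682
B,7.642
C,4.439
N,2.774
O,2.023
F,1.405
Si,13.568
P,9.155
S,7.314
Cl,5.498
Br,7.692
I,13.493
Fe,21.185
Co,18.915
Ni,17.15
Cu,15.636
Zn,14.501
Ru,24.211
Rh,21.689
Pd,12.106
Os,21.437
Ir,19.167
Pt,16.393
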