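element,value
H,0.15552
B,0.24938
C,0.2
N,0.13831
O,0.16447
F,0.14265
Si,0.29586
P,0.20492
S,0.24155
Cl,0.21368
Br,0.23697
I,0.271
Fe,0.26247
Co,0.27778
Ni,0.30769
Cu,0.30769
Zn,0.20243
Ru,0.33333
Rh,0.31646
Pd,0.25707
Os,0.26316
Ir,0.26316
Pt,0.28571
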