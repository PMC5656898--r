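symbol,z,vdw_angstrom,color_r,color_g,color_b
H,1,1.20,0.90,0.90,0.90
He,2,1.40,0.85,1.00,1.00
Li,3,1.81,0.80,0.50,1.00
Be,4,1.53,0.76,1.00,0.00
B,5,1.92,1.00,0.71,0.71
C,6,1.70,0.20,1.00,0.20
N,7,1.55,0.20,0.20,1.00
O,8,1.52,1.00,0.30,0.30
F,9,1.47,0.70,1.00,1.00
Ne,10,1.54,0.70,0.89,0.96
Na,11,2.27,0.67,0.36,0.95
Mg,12,1.73,0.54,1.00,0.00
Al,13,1.84,0.75,0.65,0.65
Si,14,2.10,0.94,0.78,0.63
P,15,1.80,1.00,0.50,0.00
S,16,1.80,0.90,0.78,0.25
Cl,17,1.75,0.12,0.94,0.12
Ar,18,1.88,0.50,0.82,0.89
K,19,2.75,0.56,0.25,0.83
Ca,20,2.31,0.24,1.00,0.00
Sc,21,2.11,0.90,0.90,0.90
Ti,22,2.00,0.75,0.76,0.78
V,23,2.00,0.65,0.65,0.67
Cr,24,2.00,0.54,0.60,0.78
Mn,25,2.00,0.61,0.48,0.78
Fe,26,2.00,0.88,0.40,0.20
Co,27,2.00,0.94,0.56,0.63
Ni,28,1.63,0.31,0.82,0.31
Cu,29,1.40,0.78,0.50,0.20
Zn,30,1.39,0.49,0.50,0.69
Ga,31,1.87,0.76,0.56,0.56
Ge,32,2.11,0.40,0.56,0.56
As,33,1.85,0.74,0.50,0.89
Se,34,1.90,1.00,0.63,0.00
Br,35,1.85,0.65,0.16,0.16
Kr,36,2.02,0.36,0.72,0.82
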