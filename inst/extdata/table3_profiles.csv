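residue,raw,stir_frying,bran_stir_frying
Thr,2.39,2.18,2.24
Val,4.87,4.71,4.74
Met,1.13,1.42,1.19
Ile,3.41,3.32,3.32
Leu,17.62,17.46,17.17
Phe,5.75,5.55,5.68
Lys,0.14,0.10,0.11
Trp,0,0,0
Asp,5.98,5.99,5.89
Tyr,4.81,4.73,4.76
Ser,4.62,4.68,4.54
Glu,27.29,27.10,26.64
Gly,0.57,0.70,0.61
Ala,12.38,12.50,12.19
His,1.12,1.09,1.08
Arg,2.23,2.23,2.15
Pro,8.34,8.20,8.22
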