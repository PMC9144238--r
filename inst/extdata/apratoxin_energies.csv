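id,label,eps_homo,eps_lumo,eps_somo_anion,e_gs_nm1,e_gs_n,e_gs_np1,unit
A,Apratoxin A,-6.24,-1.22,-1.18,,,,eV
B,Apratoxin B,-6.20,-1.74,-1.70,,,,eV
C,Apratoxin C,-6.04,-1.76,-1.73,,,,eV
D,Apratoxin D,-6.22,-1.38,-1.38,,,,eV
E,Apratoxin E,-6.08,-1.69,-1.67,,,,eV
F,Apratoxin F,-6.19,-1.40,-1.37,,,,eV
G,Apratoxin G,-6.12,-1.79,-1.77,,,,eV
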