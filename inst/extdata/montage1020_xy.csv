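label,x,y
Fp1,-0.309017,0.951057
Fp2,0.309017,0.951057
F3,-0.410105,0.506438
F4,0.410105,0.506438
Fz,0,0.500978
F7,-0.809017,0.587785
F8,0.809017,0.587785
C3,-0.500978,0
C4,0.500978,0
Cz,0,0
P3,-0.410105,-0.506438
P4,0.410105,-0.506438
Pz,0,-0.500978
O1,-0.309017,-0.951057
O2,0.309017,-0.951057
T3,-1,0
T4,1,0
T5,-0.809017,-0.587785
T6,0.809017,-0.587785
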