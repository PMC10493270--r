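Fp1 Fp2
Fp1 F3
Fp2 F4
F3 C3
F4 C4
C3 P3
C4 P4
P3 O1
P4 O2
O1 O2
Fp1 F7
F3 F7
C3 F7
Fp2 F8
F4 F8
C4 F8
C3 T3
F7 T3
C4 T4
F8 T4
C3 T5
P3 T5
O1 T5
T3 T5
C4 T6
P4 T6
O2 T6
T4 T6
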