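P1_1	P1
P2_1	P2
P3_1	P3
P4_1	P4
P4_2	P4
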