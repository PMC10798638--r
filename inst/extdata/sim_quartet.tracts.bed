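sim1	31926	65904	1
sim1	184983	200000	1
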