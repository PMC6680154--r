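group,contigs,kb,anchored
A,17,119,TRUE
B,58,888,TRUE
C,56,325,FALSE
D,99,178,FALSE
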