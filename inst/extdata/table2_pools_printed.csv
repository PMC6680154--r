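pool,interval,cm
Thrum-1,interval_1,0.62
Thrum-1,interval_2,0.39
Thrum-1,intra_S,0.00
Thrum-2,interval_1,2.55
Thrum-2,interval_2,1.53
Thrum-2,intra_S,0.13
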