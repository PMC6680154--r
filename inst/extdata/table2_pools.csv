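pool,total,interval_1,interval_2,intra_S
Thrum-1,1291,8,6,0
Thrum-2,784,20,12,1
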