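cross_id,female,male,informative,total,interval_1,interval_2,intra_S
1,Pin-1,Thrum-1,Thrum-1,146,1,0,0
2,Pin-1,Thrum-2,Thrum-2,61,0,1,0
3,Pin-1,Thrum-3,Thrum-3,299,5,2,0
4,Pin-1,Thrum-4,Thrum-4,95,1,0,0
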