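cross_id,female,male,informative,total,interval_1,interval_2,intra_S
1,Pin-1,Thrum-1,Thrum-1,413,3,2,0
2,Pin-2,Thrum-1,Thrum-1,430,2,0,0
3,Thrum-1,Pin-3,Thrum-1,448,3,3,0
4,Pin-4,Thrum-2,Thrum-2,500,6,5,0
5,Pin-5,Thrum-2,Thrum-2,116,3,6,1
6,Thrum-2,Pin-4,Thrum-2,167,11,1,0
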