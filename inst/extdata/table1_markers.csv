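marker,pin_plants,thrum_plants,total,recombinants,printed_cm,printed_bound
PvSLP1,92,99,191,0,0.52,TRUE
PvSLL1,74,100,174,0,0.57,TRUE
PvSLL2,56,90,146,2,1.37,FALSE
PvGlo,64,93,157,0,0.64,TRUE
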