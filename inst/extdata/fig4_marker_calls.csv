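individual_id,crossover_interval,morph,marker_id,allele_state,bands
1,S_to_flank2,pin,PvSLL1,pin_only_homozygous,3.0kb
4,S_to_flank2,thrum,PvSLL1,thrum_pin_heterozygous,3.0kb+2.8kb
6,S_to_flank2,pin,PvSLL1,novel_band,3.0kb+2.5kb
7,S_to_flank2,pin,PvSLL1,pin_only_homozygous,3.0kb
2,flank1_to_S,thrum,PvSLL1,thrum_pin_heterozygous,3.0kb+2.8kb
3,flank1_to_S,thrum,PvSLL1,thrum_pin_heterozygous,3.0kb+2.8kb
5,flank1_to_S,thrum,PvSLL1,thrum_pin_heterozygous,3.0kb+2.8kb
8,flank1_to_S,thrum,PvSLL1,thrum_pin_heterozygous,3.0kb+2.8kb
9,flank1_to_S,thrum,PvSLL1,thrum_pin_heterozygous,3.0kb+2.8kb
10,flank1_to_S,thrum,PvSLL1,thrum_pin_heterozygous,3.0kb+2.8kb
11,flank1_to_S,thrum,PvSLL1,thrum_pin_heterozygous,3.0kb+2.8kb
12,flank1_to_S,thrum,PvSLL1,thrum_pin_heterozygous,3.0kb+2.8kb
1,S_to_flank2,pin,PvSLL2,pin_only_homozygous,<15kb
4,S_to_flank2,thrum,PvSLL2,thrum_pin_heterozygous,<15kb+5.0kb
6,S_to_flank2,pin,PvSLL2,pin_only_homozygous,<15kb
7,S_to_flank2,pin,PvSLL2,pin_only_homozygous,<15kb
2,flank1_to_S,thrum,PvSLL2,thrum_pin_heterozygous,<15kb+5.0kb
3,flank1_to_S,thrum,PvSLL2,thrum_pin_heterozygous,<15kb+5.0kb
5,flank1_to_S,thrum,PvSLL2,thrum_pin_heterozygous,<15kb+5.0kb
8,flank1_to_S,thrum,PvSLL2,thrum_pin_heterozygous,<15kb+5.0kb
9,flank1_to_S,thrum,PvSLL2,pin_only_homozygous,<15kb
10,flank1_to_S,thrum,PvSLL2,thrum_pin_heterozygous,<15kb+5.0kb
11,flank1_to_S,thrum,PvSLL2,thrum_pin_heterozygous,<15kb+5.0kb
12,flank1_to_S,thrum,PvSLL2,thrum_pin_heterozygous,<15kb+5.0kb
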