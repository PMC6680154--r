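cross_id,OKL,S,SEP,count
1,mutant,thrum,wild_type,73
1,wild_type,pin,mutant,72
1,mutant,pin,mutant,1
1,wild_type,thrum,wild_type,0
1,mutant,thrum,mutant,0
1,wild_type,pin,wild_type,0
1,mutant,pin,wild_type,0
1,wild_type,thrum,mutant,0
2,mutant,thrum,wild_type,30
2,wild_type,pin,mutant,30
2,mutant,pin,mutant,0
2,wild_type,thrum,wild_type,0
2,mutant,thrum,mutant,1
2,wild_type,pin,wild_type,0
2,mutant,pin,wild_type,0
2,wild_type,thrum,mutant,0
3,mutant,thrum,wild_type,147
3,wild_type,pin,mutant,146
3,mutant,pin,mutant,2
3,wild_type,thrum,wild_type,2
3,mutant,thrum,mutant,1
3,wild_type,pin,wild_type,0
3,mutant,pin,wild_type,1
3,wild_type,thrum,mutant,0
4,mutant,thrum,wild_type,47
4,wild_type,pin,mutant,47
4,mutant,pin,mutant,1
4,wild_type,thrum,wild_type,0
4,mutant,thrum,mutant,0
4,wild_type,pin,wild_type,0
4,mutant,pin,wild_type,0
4,wild_type,thrum,mutant,0
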