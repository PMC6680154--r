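cross_id,OKL,S,HIH,count
1,wild_type,thrum,mutant,204
1,mutant,pin,wild_type,204
1,wild_type,pin,wild_type,2
1,mutant,thrum,mutant,1
1,wild_type,thrum,wild_type,1
1,mutant,pin,mutant,1
1,wild_type,pin,mutant,0
1,mutant,thrum,wild_type,0
2,wild_type,thrum,mutant,214
2,mutant,pin,wild_type,214
2,wild_type,pin,wild_type,1
2,mutant,thrum,mutant,1
2,wild_type,thrum,wild_type,0
2,mutant,pin,mutant,0
2,wild_type,pin,mutant,0
2,mutant,thrum,wild_type,0
3,wild_type,thrum,mutant,221
3,mutant,pin,wild_type,221
3,wild_type,pin,wild_type,2
3,mutant,thrum,mutant,1
3,wild_type,thrum,wild_type,2
3,mutant,pin,mutant,1
3,wild_type,pin,mutant,0
3,mutant,thrum,wild_type,0
4,wild_type,thrum,mutant,245
4,mutant,pin,wild_type,244
4,wild_type,pin,wild_type,3
4,mutant,thrum,mutant,3
4,wild_type,thrum,wild_type,3
4,mutant,pin,mutant,2
4,wild_type,pin,mutant,0
4,mutant,thrum,wild_type,0
5,wild_type,thrum,mutant,53
5,mutant,pin,wild_type,53
5,wild_type,pin,wild_type,2
5,mutant,thrum,mutant,1
5,wild_type,thrum,wild_type,3
5,mutant,pin,mutant,3
5,wild_type,pin,mutant,0
5,mutant,thrum,wild_type,0
5,wild_type,short_homostyle,mutant,1
6,wild_type,thrum,mutant,78
6,mutant,pin,wild_type,77
6,wild_type,pin,wild_type,6
6,mutant,thrum,mutant,5
6,wild_type,thrum,wild_type,1
6,mutant,pin,mutant,0
6,wild_type,pin,mutant,0
6,mutant,thrum,wild_type,0
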