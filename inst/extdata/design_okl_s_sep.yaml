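loci:
  - name: OKL
    dominance: mutant_dominant
    dominant: OKL
    recessive: okl
  - name: S
    dominance: composite_S
    dominant: GPA
    recessive: gpa
  - name: SEP
    dominance: mutant_recessive
    dominant: SEP
    recessive: sep
parents:
  - id: Thrum-1
    role: informative
    haplotype_1: "OKL,GPA,SEP"
    haplotype_2: "okl,gpa,sep"
  - id: Thrum-2
    role: informative
    haplotype_1: "OKL,GPA,SEP"
    haplotype_2: "okl,gpa,sep"
  - id: Thrum-3
    role: informative
    haplotype_1: "OKL,GPA,SEP"
    haplotype_2: "okl,gpa,sep"
  - id: Thrum-4
    role: informative
    haplotype_1: "OKL,GPA,SEP"
    haplotype_2: "okl,gpa,sep"
  - id: Pin-sep
    role: tester
    haplotype_1: "okl,gpa,sep"
    haplotype_2: "okl,gpa,sep"
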