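loci:
  - name: OKL
    dominance: mutant_dominant
    dominant: OKL
    recessive: okl
  - name: S
    dominance: composite_S
    dominant: GPA
    recessive: gpa
  - name: HIH
    dominance: mutant_dominant
    dominant: HIH
    recessive: hih
parents:
  - id: Thrum-1
    role: informative
    haplotype_1: "okl,GPA,HIH"
    haplotype_2: "OKL,gpa,hih"
  - id: Thrum-2
    role: informative
    haplotype_1: "okl,GPA,HIH"
    haplotype_2: "OKL,gpa,hih"
  - id: Pin-tester
    role: tester
    haplotype_1: "okl,gpa,hih"
    haplotype_2: "okl,gpa,hih"
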