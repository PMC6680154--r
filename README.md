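# slocusmap

Classical three-point testcross linkage analysis for the *Primula
vulgaris* *S* locus — the supergene that controls heterostyly (the
reciprocal pin/thrum floral polymorphism) — together with the
surrounding inference steps a heterostyly mapping study needs:
zero-recombinant distance bounds, placement of molecular markers from
recombinant progeny, and genetic-to-physical map scaling. A multinomial
meiosis simulator with configurable interference and a rare intra-*S*
recombination rate (the classical source of self-fertile homostyles)
lets every estimator be validated by parameter recovery.

## The genetics

The *S* locus is modelled classically as three tightly linked diallelic
sub-genes **G** (style length), **P** (pollen size) and **A** (anther
height): thrums are heterozygous *GPA/gpa*, pins homozygous *gpa/gpa*.
Rare crossovers within the supergene yield recombinant haplotypes such
as *GPa*, which over a *gpa* gamete gives a self-fertile short
homostyle with large pollen.

In a three-point testcross over loci in order 1–*S*–2, a heterozygous
(informative) parent crossed to a fully homozygous tester produces
eight progeny classes in four reciprocal pairs. With interval
recombination fractions r₁, r₂ and coefficient of coincidence *c*:

    P(double)   = c·r₁·r₂          P(single, interval 1) = r₁ − c·r₁·r₂
    P(parental) = 1 − r₁ − r₂ + c·r₁·r₂   P(single, interval 2) = r₂ − c·r₁·r₂

The rarest reciprocal pair identifies the double crossovers and hence
the middle locus; map distance is the raw recombination percentage
(1 cM = 1% recombinant gametes, no mapping-function correction);
*c* = observed doubles / (r₁·r₂·N) and interference I = 1 − *c*.
Where zero recombinants are seen among N progeny, the distance is
bounded by one hypothetical recombinant: < 100/N cM.

## Worked example

```r
library(slocusmap)

design <- design_okl_s_hih()          # Oakleaf - S - Hose in Hose
res <- analyze_threepoint(table2_crosses(), design,
                          declared = table2_declared(),
                          pools    = table2_pools())
print(res)
```

```
    pool   interval count total        cm cm_printed bound
 Thrum-1 interval_1     8  1291 0.6196747       0.62 FALSE
 Thrum-1 interval_2     6  1291 0.4647560       0.46 FALSE
 Thrum-2 interval_1    20   784 2.5510204       2.55 FALSE
 Thrum-2 interval_2    12   784 1.5306122       1.53 FALSE
 Thrum-2    intra_S     1   784 0.1275510       0.13 FALSE
 ...
From pooled progeny: Inferred gene order: OKL - S - HIH

Flags:
 ! pool Thrum-1 interval_2: printed 0.39 cM but tabulated count gives 6/1291 = 0.46 cM
```

The two thrum parents give *Oakleaf*–*S* distances of 0.62 and 2.55 cM
and *S*–*Hose in Hose* distances of 0.46 and 1.53 cM; the single short
homostyle among 784 progeny dates an intra-*S* crossover at 0.13 cM
across the supergene (0.05 cM over all 2075 progeny). The flag marks a
cell of the source table whose printed distance cannot be reproduced
from its own printed count — the package computes, it does not copy.

Marker placement and scaling work the same way:

```r
calls <- fig4_marker_calls()
place_marker(calls[calls$marker_id == "PvSLL2", ], "PvSLL2",
             phase = "coupling", flank1 = "OKL", flank2 = "HIH")
#> Marker PvSLL2 placement: between OKL and S
marker_distance(1, 2075)      #> 1/2075 recombinants: 0.05 cM
range_scaling(888, c(0.39, 1.53))  #> 580 and 2277 kb per cM
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study end to end and
write TSV reports under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | simulator validation and parameter recovery |
| `02_threepoint_hih.R` | *Oakleaf*–*S*–*Hose in Hose* three-point analysis |
| `03_threepoint_sep.R` | *Oakleaf*–*S*–*sepaloid* three-point analysis |
| `04_single_markers.R` | single-marker cosegregation bounds |
| `05_marker_placement.R` | RFLP marker placement from recombinants |
| `06_physical_scaling.R` | kb-per-cM scaling and separation bounds |

Run any of them from the repository root, e.g.
`Rscript analysis/02_threepoint_hih.R`.

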