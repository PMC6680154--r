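---
title: "Three-point testcross mapping of the Primula S locus: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-point testcross mapping of the Primula S locus: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slocusmap)
```

## The model

Heterostyly in *Primula* is controlled by the *S* locus, treated here in
its classical formulation as three tightly linked diallelic sub-genes in
fixed order **G**–**P**–**A**: G short style, P large pollen, A high
anthers, each dominant. Thrums are *GPA/gpa*, pins *gpa/gpa*. The floral
morph follows deterministically from the diploid genotype: thrum =
short style + high anthers, pin = long + low, and the two mixed
combinations are self-fertile homostyles (short homostyle = short
style + low anthers; long homostyle = the reverse). Pollen size is
reported alongside the morph — it is what distinguishes, say, a
*GPa/gpa* short homostyle (large pollen) from a *Gpa/gpa* one (small) —
but is never used for crossover classification, because the flanking
phenotypes plus morph already identify the gamete.

A three-point testcross crosses an informative parent, heterozygous at
two flanking phenotypic loci and at *S*, to a tester whose gametes can
mask nothing (homozygous at every scored locus; the constructor
enforces this). The informative parent's eight gametes fall into four
reciprocal pairs — parental, single crossover in either interval, and
double crossover — and with the tester fixed, each gamete maps to a
distinct progeny phenotype, so phenotype classification inverts the
gamete enumeration exactly (`classify_progeny` is tested as the inverse
of `phenotype_of` over all eight gametes).

Phase is encoded only through the two explicit haplotypes of each
parent. Coupling/repulsion labels are derived output (`parent_phase`),
never input: multi-locus textual phase notation is ambiguous, two
ordered haplotypes are not.

## Estimators

* **Gene order** (`infer_order`): double crossovers exchange exactly the
  middle locus relative to a parental gamete, so the order is the one
  under which the observed rarest non-parental reciprocal pair is the
  double-crossover pair. Ties for rarest yield an explicit ambiguity
  flag with no order reported — never an arbitrary choice — and a table
  with no recombinants at all is returned as indeterminate rather than
  raising an error. Orders are reversal-invariant; `canonical_order`
  fixes an orientation for comparison.
* **Map distance** (`interval_distance`): the plain recombination
  percentage 100·k/N. No Haldane or Kosambi correction is applied at
  these distances (all under 3 cM, where the corrections are far below
  the printed precision); both transforms are exported
  (`haldane_cm`, `kosambi_cm`) as clearly opt-in extras.
* **Zero-recombinant bound** (`zero_recombinant_bound`): with k = 0 the
  point estimate is degenerate, so the distance implied by one
  hypothetical recombinant, 100/N, is reported as a "<" upper bound.
  Numerically it equals `interval_distance(1, N)`, and a test enforces
  that identity.
* **Coincidence** (`coincidence`): c = observed doubles /(r₁·r₂·N) with
  r taken from the two interval estimates on the same N; interference
  I = 1 − c holds identically by construction. When the expected count
  is zero the result is flagged undefined rather than infinite.
* **Intra-S distance** (`exceptional_class_distance`): homostyle
  progeny are excluded from both flanking intervals and counted in
  their own column; their frequency dates recombination across the
  supergene itself. Which parent's meiosis produced a homostyle is not
  observable from the phenotype; the model books intra-S events to the
  informative parent, the only one whose recombination is visible at
  all in a testcross.

### Counting conventions

Published three-point tables differ in whether an interval's
"recombinants" column includes double crossovers. The default here,
`column_as_printed`, takes tabulated counts verbatim — that is the
arithmetic by which such tables' distance columns are computed, and it
is the only faithful option when the class-level data behind a printed
table are unavailable. When class counts are available, the standard
`singles_plus_doubles` tabulation (each double counts once in each
interval) is derived instead. For the packaged sepaloid-cross fixture
the two agree by construction: the printed interval counts are
consistent with the published pooled class counts (6/2/1) only if the
one double crossover is included in both of its intervals.

### Tabulated totals as authoritative inputs

Published tables print their own pooled totals rows, and those rows are
what downstream arithmetic in the source used. `analyze_threepoint`
therefore accepts tabulated pools (`as_pool`) alongside per-cross
records, uses the pools for distance arithmetic, and cross-checks the
two forms. In the packaged Hose in Hose table this surfaces three
genuine internal inconsistencies, which the report carries as
first-class flags rather than silently resolving: a pooled total of 784
against cross totals summing to 783; a pooled S-side recombinant count
of 6 against cells summing to 5; and a printed distance of 0.39 cM
where the printed count gives 6/1291 = 0.46 cM. Declared printed
distances are kept as metadata so the report can show both the
computed range and the as-printed range.

## The simulator

`simulate_cross` draws one multinomial sample of size N over the four
gamete categories with P(double) = c·r₁·r₂ and the single/parental
probabilities that follow, then splits each category binomially between
its two reciprocal gametes (meiotic sampling, not forced equality).
Interference is represented by the single coincidence multiplier c —
deliberately the same parameter the estimator reports, so parameter
recovery closes the loop — rather than by a chi-square/gamma renewal
process. Independently of the flanking intervals, each meiosis
recombines within *S* with probability h, replacing the transmitted
*S* haplotype by a single-crossover product with the breakpoint uniform
over the G–P and P–A sub-intervals; h defaults to 0 and the study-scale
value used in validation scripts is 1/784, one homostyle per 784
progeny. All draws flow from one seeded generator stream, so a config
plus seed reproduces a table bitwise.

Defaults in the validation scripts mirror the study conditions:
r₁ = 0.014, r₂ = 0.008 (the pooled-scale recombination fractions),
c = 1, N = 2075. `simulate_marker_calls` adds an RFLP-style marker
whose thrum allele is coupled to *S*: the marker allele travels with
the chromosome segment carrying it, and inside a flank–*S* interval a
crossover separates marker from *S* with conditional probability
(marker–*S* fraction)/(interval fraction).

What the simulator does **not** emulate: sex-specific recombination
rates (pools are per-parent, so a single r per parent suffices),
chiasma-level interference structure beyond the coincidence multiplier,
genotyping error, segregation distortion, and any joint dependence
between intra-*S* events and flanking crossovers (no data exist to
calibrate one). Passing parameter-recovery tests therefore demonstrates
estimator correctness under multinomial sampling, not robustness to
those real-data complications.

## Marker placement

`cosegregation_verdict` compares a recombinant's marker zygosity
against the expectation if the marker stayed coupled to its *S*-side
allele (thrum recombinants should stay heterozygous, pin recombinants
pin-homozygous). Placement logic per flank F: all informative
recombinants in the F–*S* interval also recombined the marker — marker
distal to F; all kept it with *S* — distal to F excluded; a mixture —
marker between F and *S*. Only the coupling phase (thrum allele on the
*S* haplotype) is supported, and it must be stated explicitly.

Novel bands are never auto-interpreted: they may be restriction-site
mutations or genuine recombinants, so the verdict is uninformative with
a flag, and `place_marker`/`marker_distance` report both readings (a
point distance if recombination, a "≤" bound if mutation). Dominant
presence/absence markers (RAPD-like) are refused with an explanatory
error, since zygosity cannot be read from band presence. Marker
distances use the full screened progeny count as denominator, not the
blotted subset — the blot only identifies which recombinant carries the
event; the screen defines the population it occurred in.

## Numerical choices

* Printed-precision values use half-up rounding (`round_half_up`), two
  decimals for cM and whole kb for physical scaling, matching how
  linkage tables are conventionally printed; base R's half-to-even
  would disagree on exact halves.
* Distances are reported both exact and rounded; comparisons against
  declared printed values use the rounded form.
* Degenerate inputs are errors with directed messages: zero totals,
  infeasible coincidence (with the feasibility bound on c shown),
  testers heterozygous at a scored locus, markers whose distance to *S*
  exceeds their containing interval.
* Unscored phenotype entries are tolerated and propagate: an individual
  is classified only if its scored loci identify a unique category,
  otherwise it is a located error.

## Problem sizes

The test suite validates estimators at the scale where the binomial
approximations it asserts are sharp and the suite stays fast: 200 seeds
of N = 10⁵ category draws for recovery and coincidence calibration
(category-level draws, so this is cheap), 100 simulated placements of
N = 5000 progeny for marker-position recovery, and 50 random designs
for the enumeration and classification properties. The full suite runs
in well under a minute on one CPU.

## Limitations

* Map distances are raw recombination percentages; over long intervals
  they are not additive (use the exported mapping functions if that
  matters — it does not at sub-3-cM scales).
* The coincidence estimator needs the double-crossover count, which
  published interval columns may or may not include; where a source
  table does not restate per-pool doubles, c cannot be reconstructed
  from it, and the package documents that rather than guessing.
* Placement evidence from a handful of recombinants excludes positions
  and supports intervals; it cannot order markers within an interval —
  that requires sequence, which is out of scope here (contig lengths
  enter only as numbers for `kb_per_cm`/`separation_bound`).
* The G–P–A sub-gene model is the classical formalism; the package
  makes no claim about the molecular identity of the sub-genes.
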