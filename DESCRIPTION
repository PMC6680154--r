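Package: slocusmap
Title: Three-Point Testcross Linkage Mapping of the Primula S Locus
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classical-genetics inference for heterostyly mapping in
    Primula vulgaris: phase- and dominance-aware three-point testcross
    analysis (gene order from the rarest reciprocal progeny pair,
    per-parent interval distances in centimorgans, coefficient of
    coincidence and crossover interference), zero-recombinant upper
    bounds on map distance, placement of molecular markers relative to
    the S locus from recombinant progeny, and genetic-to-physical map
    scaling (kb per cM). Includes a multinomial meiosis simulator with
    configurable recombination fractions, coincidence, and a rare
    intra-S recombination rate generating self-fertile homostyles, so
    every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
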