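# Dominance rules, gamete enumeration and progeny classification.

test_that("S-locus dominance rules give the classical morphs", {
  d <- design_okl_s_hih()
  thrum <- phenotype_of(c("okl", "GPA", "HIH"), c("okl", "gpa", "hih"), d)
  expect_equal(unname(thrum["S"]), "thrum")
  expect_equal(attr(thrum, "pollen"), "large")

  pin <- phenotype_of(c("okl", "gpa", "hih"), c("okl", "gpa", "hih"), d)
  expect_equal(unname(pin["S"]), "pin")
  expect_equal(attr(pin, "pollen"), "small")
  expect_false(attr(pin, "self_fertile"))

  # the G-P-retaining, A-losing recombinant over the pin haplotype is a
  # self-fertile short homostyle with large pollen
  sh <- phenotype_of(c("okl", "GPa", "hih"), c("okl", "gpa", "hih"), d)
  expect_equal(unname(sh["S"]), "short_homostyle")
  expect_equal(attr(sh, "pollen"), "large")
  expect_true(attr(sh, "self_fertile"))

  # Hose in Hose is dominant
  expect_equal(unname(thrum["HIH"]), "mutant")
})

test_that("all 8 S haplotypes over the pin tester map to the expected morphs", {
  d <- design_okl_s_hih()
  g <- c("G", "g"); p <- c("P", "p"); a <- c("A", "a")
  for (gi in g) for (pi in p) for (ai in a) {
    hap <- paste0(gi, pi, ai)
    ph <- phenotype_of(c("okl", hap, "hih"), c("okl", "gpa", "hih"), d)
    expected_morph <-
      if (gi == "G" && ai == "A") "thrum"
      else if (gi == "g" && ai == "a") "pin"
      else if (gi == "G") "short_homostyle"
      else "long_homostyle"
    expect_equal(unname(ph["S"]), expected_morph, info = hap)
    expect_equal(attr(ph, "pollen"), if (pi == "P") "large" else "small",
                 info = hap)
  }
  # the short homostyle with large pollen pins down GPa uniquely among
  # single-crossover products of GPA/gpa
  singles <- c("Gpa", "gPA", "GPa", "gpA")
  match_pheno <- vapply(singles, function(hap) {
    ph <- phenotype_of(c("okl", hap, "hih"), c("okl", "gpa", "hih"), d)
    ph[["S"]] == "short_homostyle" && attr(ph, "pollen") == "large"
  }, logical(1))
  expect_equal(names(match_pheno)[match_pheno], "GPa")
})

test_that("recessive loci need two recessive alleles for the mutant phenotype", {
  d <- design_okl_s_sep()
  het <- phenotype_of(c("OKL", "GPA", "SEP"), c("okl", "gpa", "sep"), d)
  expect_equal(unname(het["SEP"]), "wild_type")
  hom <- phenotype_of(c("okl", "gpa", "sep"), c("okl", "gpa", "sep"), d)
  expect_equal(unname(hom["SEP"]), "mutant")
})

test_that("phase is derived from the haplotypes, not supplied", {
  d <- design_okl_s_hih()
  ph <- parent_phase("Thrum-1", d)
  expect_true(all(ph$heterozygous))
  get_phase <- function(a, b) ph$phase$phase[
    (ph$phase$locus_a == a & ph$phase$locus_b == b) |
    (ph$phase$locus_a == b & ph$phase$locus_b == a)]
  expect_equal(get_phase("S", "HIH"), "coupling")
  expect_equal(get_phase("OKL", "S"), "repulsion")
})

test_that("haplotype and design validation reject malformed input", {
  d <- design_okl_s_hih()
  expect_error(phenotype_of(c("okl", "GPA"), c("okl", "gpa", "hih"), d),
               "length")
  expect_error(phenotype_of(c("okl", "GXA", "hih"), c("okl", "gpa", "hih"), d),
               "G/g,P/p,A/a")
  expect_error(phenotype_of(c("BAD", "GPA", "hih"), c("okl", "gpa", "hih"), d),
               "unknown at locus")
  expect_error(cross_design(list(locus("A", "mutant_dominant", "A", "a"),
                                 locus("A", "mutant_dominant", "A", "a"))),
               "duplicate")
  expect_error(cross_design(list(locus("S1", "composite_S"),
                                 locus("S2", "composite_S"))),
               "at most one")
  expect_error(
    cross_design(list(locus("A", "mutant_dominant", "A", "a")),
                 list(parent_genotype("t", "A", "a", "tester"))),
    "homozygous")
})

test_that("gamete enumeration gives 4 complementary pairs covering 8 gametes", {
  d <- design_okl_s_hih()
  cls <- enumerate_gamete_classes("Thrum-1", d)
  expect_named(cls, c("parental", "single_interval_1", "single_interval_2",
                      "double"))
  # double pair: Hose in Hose pin and Oakleaf thrum
  dbl <- lapply(cls$double, function(h)
    phenotype_of(h, c("okl", "gpa", "hih"), d))
  morphs <- vapply(dbl, function(p) p[["S"]], character(1))
  expect_setequal(morphs, c("pin", "thrum"))
  hih_pin <- dbl[[which(morphs == "pin")]]
  expect_equal(unname(hih_pin[c("OKL", "HIH")]),
               c("wild_type", "mutant"))
  okl_thrum <- dbl[[which(morphs == "thrum")]]
  expect_equal(unname(okl_thrum[c("OKL", "HIH")]),
               c("mutant", "wild_type"))
  # parental pair: Hose in Hose thrum and Oakleaf pin
  par <- lapply(cls$parental, function(h)
    phenotype_of(h, c("okl", "gpa", "hih"), d))
  pm <- vapply(par, function(p) p[["S"]], character(1))
  expect_equal(unname(par[[which(pm == "thrum")]][c("OKL", "HIH")]),
               c("wild_type", "mutant"))
  expect_equal(unname(par[[which(pm == "pin")]][c("OKL", "HIH")]),
               c("mutant", "wild_type"))
  # union of pairs: 8 distinct haplotypes; pair members are complements
  all_keys <- unlist(lapply(cls, function(pair) vapply(pair, hap_key, "")))
  expect_length(unique(all_keys), 8)
  for (pair in cls) {
    expect_true(all(pair[[1]] != pair[[2]]))
  }
  expect_error(
    enumerate_gamete_classes(
      parent_genotype("hom", c("okl", "GPA", "HIH"), c("okl", "gpa", "hih")),
      d),
    "homozygous at locus OKL")
})

test_that("enumeration matches brute force over 50 random designs", {
  for (seed in 1:50) {
    d <- random_design(seed)
    inf <- d$parents[["inf"]]
    got <- enumerate_gamete_classes(inf, d)
    want <- oracle_gamete_classes(inf$hap1, inf$hap2)
    for (cat in names(want)) {
      expect_setequal(vapply(got[[cat]], hap_key, ""),
                      vapply(want[[cat]], hap_key, ""))
    }
  }
})

test_that("classification inverts phenotype over all gametes (round trip)", {
  for (seed in c(3, 17, 29, 41)) {
    d <- random_design(seed)
    inf <- d$parents[["inf"]]; tst <- d$parents[["tst"]]
    cls <- enumerate_gamete_classes(inf, d)
    seen <- character(0)
    for (cat in names(cls)) for (g in cls[[cat]]) {
      ph <- phenotype_of(g, tst$hap1, d)
      expect_equal(classify_progeny(ph, inf, tst, d), cat)
      seen <- c(seen, paste(ph[d$locus_names], collapse = "|"))
    }
    # testcross informativeness: all 8 phenotypes distinct
    expect_length(unique(seen), 8)
  }
})

test_that("homostyle morphs classify as intra-S recombinants", {
  d <- design_okl_s_hih()
  ph <- c(OKL = "wild_type", S = "short_homostyle", HIH = "mutant")
  expect_equal(classify_progeny(ph, "Thrum-1", d$parents[["Pin-tester"]], d),
               "intra_S")
})

test_that("impossible phenotypes raise a data error naming the individual", {
  # with a fully heterozygous informative parent and recessive tester,
  # every three-locus phenotype is reachable; a contaminant only shows
  # up against a tester that fixes a phenotype. Here the tester is
  # homozygous for the dominant allele at locus 1, so wild_type progeny
  # there are impossible (e.g. pollen contamination from another plot).
  d <- cross_design(
    list(locus("A", "mutant_dominant", "A", "a"),
         locus("S", "composite_S"),
         locus("B", "mutant_dominant", "B", "b")),
    list(parent_genotype("inf", c("a", "GPA", "B"), c("A", "gpa", "b"),
                         "informative"),
         parent_genotype("tst", c("A", "gpa", "b"), c("A", "gpa", "b"),
                         "tester")))
  ph <- c(A = "wild_type", S = "pin", B = "wild_type")
  expect_error(
    classify_progeny(ph, "inf", "tst", d, individual_id = "plant-X"),
    "plant-X.*no gamete")
})

test_that("unscored loci are tolerated when the rest identifies the category", {
  d <- design_okl_s_hih()
  tst <- d$parents[["Pin-tester"]]
  # OKL unscored: thrum + HIH-mutant is parental-or-single1; ambiguous
  expect_error(
    classify_progeny(c(OKL = "unscored", S = "thrum", HIH = "mutant"),
                     "Thrum-1", tst, d),
    "unique")
  # HIH unscored with OKL mutant + thrum: single_interval_1 vs double
  # share OKL=mutant? single1 gamete 2 is (OKL,GPA,HIH): mutant thrum;
  # double gamete 2 is (OKL,GPA,hih): mutant thrum wild-type. With HIH
  # unscored both match -> ambiguous; scoring HIH resolves it
  expect_equal(
    classify_progeny(c(OKL = "mutant", S = "thrum", HIH = "mutant"),
                     "Thrum-1", tst, d),
    "single_interval_1")
  expect_equal(
    classify_progeny(c(OKL = "mutant", S = "thrum", HIH = "wild_type"),
                     "Thrum-1", tst, d),
    "double")
})
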