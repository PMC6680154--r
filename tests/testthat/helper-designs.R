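# Shared builders for tests: random three-locus testcross designs and a
# brute-force gamete-class oracle independent of the package's
# crossover-placement construction.

random_design <- function(seed) {
  set.seed(seed)
  pos_s <- if (stats::runif(1) < 0.5) sample(1:3, 1) else 0L
  loci <- lapply(1:3, function(i) {
    nm <- paste0("L", i)
    if (i == pos_s) locus(nm, "composite_S")
    else locus(nm, sample(c("mutant_dominant", "mutant_recessive"), 1),
               paste0("D", i), paste0("d", i))
  })
  # random phase: each heterozygous locus puts its dominant allele on a
  # random homolog
  h1 <- character(3); h2 <- character(3)
  for (i in 1:3) {
    l <- loci[[i]]
    if (stats::runif(1) < 0.5) { h1[i] <- l$dominant; h2[i] <- l$recessive }
    else { h1[i] <- l$recessive; h2[i] <- l$dominant }
  }
  tester_hap <- vapply(loci, function(l) l$recessive, character(1))
  cross_design(loci, list(
    parent_genotype("inf", h1, h2, "informative"),
    parent_genotype("tst", tester_hap, tester_hap, "tester")))
}

# enumerate all 2^3 chromosome-of-origin combinations and categorise by
# strand switches between adjacent loci
oracle_gamete_classes <- function(h1, h2) {
  grid <- expand.grid(o1 = 1:2, o2 = 1:2, o3 = 1:2)
  cat <- apply(grid, 1, function(o) {
    sw1 <- o[1] != o[2]; sw2 <- o[2] != o[3]
    if (!sw1 && !sw2) "parental"
    else if (sw1 && !sw2) "single_interval_1"
    else if (!sw1 && sw2) "single_interval_2"
    else "double"
  })
  haps <- rbind(h1, h2)
  lapply(split(seq_len(8), cat), function(idx)
    lapply(idx, function(i)
      vapply(1:3, function(j) haps[grid[i, j], j], character(1))))
}

hap_key <- function(h) paste(h, collapse = "|")

# marker-call table for placement, built from simulated single-crossover
# recombinants with their true categories
sim_placement_calls <- function(sim, marker_calls) {
  ind <- sim$individuals
  rec1 <- ind$true_category == "single_interval_1"
  rec2 <- ind$true_category == "single_interval_2"
  s_name <- "S"
  rbind(
    data.frame(individual_id = ind$individual_id[rec1],
               crossover_interval = "flank1_to_S",
               morph = ind[[s_name]][rec1],
               allele_state = marker_calls$allele_state[rec1],
               stringsAsFactors = FALSE),
    data.frame(individual_id = ind$individual_id[rec2],
               crossover_interval = "S_to_flank2",
               morph = ind[[s_name]][rec2],
               allele_state = marker_calls$allele_state[rec2],
               stringsAsFactors = FALSE))
}
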