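#' Define a scored locus
#'
#' A locus in a cross design carries a dominance mode that maps diploid
#' genotypes to observable phenotypes. `mutant_dominant` loci (e.g. the
#' Oakleaf and Hose in Hose mutations) show the mutant phenotype with one
#' or two dominant alleles; `mutant_recessive` loci (e.g. sepaloid) need
#' two recessive alleles. `composite_S` marks the heterostyly supergene,
#' modelled classically as three linked diallelic sub-genes G (style
#' length), P (pollen size) and A (anther height), written as a
#' three-letter allele string such as "GPA" (thrum haplotype) or "gpa"
#' (pin haplotype).
#'
#' @param name locus identifier, unique within a design
#' @param dominance one of "mutant_dominant", "mutant_recessive",
#'   "composite_S"
#' @param dominant symbol of the dominant allele ("GPA" for the S locus)
#' @param recessive symbol of the recessive allele ("gpa" for the S locus)
#' @return an object of class `slocus_locus`
#' @export
#' @examples
#' locus("HIH", "mutant_dominant", "HIH", "hih")
#' locus("S", "composite_S")
locus <- function(name, dominance = c("mutant_dominant", "mutant_recessive",
                                      "composite_S"),
                  dominant = NULL, recessive = NULL) {
  dominance <- match.arg(dominance)
  if (dominance == "composite_S") {
    dominant <- dominant %||% "GPA"
    recessive <- recessive %||% "gpa"
  }
  if (is.null(dominant) || is.null(recessive))
    stop_design("locus '", name, "': dominant and recessive allele symbols required")
  structure(list(name = name, dominance = dominance,
                 dominant = dominant, recessive = recessive),
            class = "slocus_locus")
}

#' Assemble a cross design
#'
#' The order of `loci` is the declared locus order; it is never inferred
#' from data. At most one locus may be the composite S locus.
#'
#' @param loci list of [locus()] objects, in map order
#' @param parents optional list of [parent_genotype()] objects
#' @return an object of class `slocus_design`
#' @export
cross_design <- function(loci, parents = list()) {
  nm <- vapply(loci, function(l) l$name, character(1))
  if (anyDuplicated(nm))
    stop_design("duplicate locus names: ", paste(nm[duplicated(nm)], collapse = ", "))
  n_s <- sum(vapply(loci, function(l) l$dominance == "composite_S", logical(1)))
  if (n_s > 1) stop_design("at most one composite_S locus per design")
  names(loci) <- nm
  design <- structure(list(loci = loci, locus_names = nm, parents = list()),
                      class = "slocus_design")
  for (p in parents) design <- add_parent(design, p)
  design
}

#' @export
print.slocus_design <- function(x, ...) {
  cat("Cross design:", paste(x$locus_names, collapse = " - "), "\n")
  for (l in x$loci)
    cat(sprintf("  %-6s %-16s %s/%s\n", l$name, l$dominance, l$dominant, l$recessive))
  for (p in x$parents)
    cat(sprintf("  parent %s (%s): %s / %s\n", p$id, p$role,
                paste(p$hap1, collapse = ","), paste(p$hap2, collapse = ",")))
  invisible(x)
}

validate_s_allele <- function(a) {
  ok <- nchar(a) == 3 &&
    substr(a, 1, 1) %in% c("G", "g") &&
    substr(a, 2, 2) %in% c("P", "p") &&
    substr(a, 3, 3) %in% c("A", "a")
  if (!ok) stop_design("invalid S-locus haplotype '", a,
                       "': expected a G/g,P/p,A/a triple such as 'GPa'")
  a
}

validate_haplotype <- function(hap, design) {
  if (is.character(hap) && length(hap) == 1 && grepl(",", hap))
    hap <- trimws(strsplit(hap, ",")[[1]])
  if (length(hap) != length(design$loci))
    stop_design("haplotype length ", length(hap), " does not match design (",
                length(design$loci), " loci)")
  for (i in seq_along(hap)) {
    l <- design$loci[[i]]
    if (l$dominance == "composite_S") validate_s_allele(hap[i])
    else if (!hap[i] %in% c(l$dominant, l$recessive))
      stop_design("allele '", hap[i], "' unknown at locus ", l$name)
  }
  unname(hap)
}

#' Define a parent by its two phased haplotypes
#'
#' Phase (coupling/repulsion) is encoded only through the two explicit
#' haplotypes; textual phase annotations are derived from them, never
#' supplied. A `tester` parent must be homozygous at every scored locus
#' so that its gamete can never mask the informative parent's allele.
#'
#' @param id parent identifier
#' @param hap1,hap2 haplotypes: character vectors of allele symbols in
#'   design locus order, or a single comma-separated string such as
#'   `"okl,GPA,HIH"`
#' @param role "informative" or "tester"
#' @return an object of class `slocus_parent`
#' @export
parent_genotype <- function(id, hap1, hap2, role = c("informative", "tester")) {
  role <- match.arg(role)
  structure(list(id = id, hap1 = hap1, hap2 = hap2, role = role),
            class = "slocus_parent")
}

add_parent <- function(design, parent) {
  parent$hap1 <- validate_haplotype(parent$hap1, design)
  parent$hap2 <- validate_haplotype(parent$hap2, design)
  if (parent$role == "tester" && any(parent$hap1 != parent$hap2))
    stop_design("tester parent '", parent$id,
                "' must be homozygous at every scored locus")
  design$parents[[parent$id]] <- parent
  design
}

get_parent <- function(design, id_or_parent) {
  if (inherits(id_or_parent, "slocus_parent")) return(id_or_parent)
  p <- design$parents[[id_or_parent]]
  if (is.null(p)) stop_design("unknown parent '", id_or_parent, "'")
  p
}

#' Heterozygous loci and phase of a parent
#'
#' Derived output: which loci are heterozygous, and for each pair of
#' heterozygous dominant alleles whether they lie in coupling (same
#' haplotype) or repulsion.
#'
#' @param parent a [parent_genotype()]
#' @param design the [cross_design()]
#' @return list with `heterozygous` (logical by locus) and `phase`
#'   (data.frame of locus pairs with coupling/repulsion labels)
#' @export
parent_phase <- function(parent, design) {
  parent <- get_parent(design, parent)
  het <- parent$hap1 != parent$hap2
  names(het) <- design$locus_names
  idx <- which(het)
  pairs <- if (length(idx) >= 2) utils::combn(idx, 2) else
    matrix(integer(0), nrow = 2)
  dom_on_hap1 <- vapply(seq_along(design$loci), function(i) {
    l <- design$loci[[i]]
    if (l$dominance == "composite_S") grepl("G", parent$hap1[i]) else
      parent$hap1[i] == l$dominant
  }, logical(1))
  phase <- data.frame(
    locus_a = design$locus_names[pairs[1, ]],
    locus_b = design$locus_names[pairs[2, ]],
    phase = ifelse(dom_on_hap1[pairs[1, ]] == dom_on_hap1[pairs[2, ]],
                   "coupling", "repulsion"),
    stringsAsFactors = FALSE)
  list(heterozygous = het, phase = phase)
}

s_traits <- function(a1, a2) {
  list(style_short = grepl("G", a1) || grepl("G", a2),
       pollen_large = grepl("P", a1) || grepl("P", a2),
       anthers_high = grepl("A", a1) || grepl("A", a2))
}

morph_from_traits <- function(tr) {
  if (tr$style_short && tr$anthers_high) "thrum"
  else if (!tr$style_short && !tr$anthers_high) "pin"
  else if (tr$style_short) "short_homostyle"
  else "long_homostyle"
}

#' Phenotype of a diploid genotype
#'
#' Applies each locus's dominance rule. At the composite S locus the
#' style is short iff at least one G allele is present, anthers are high
#' iff at least one A, and pollen is large iff at least one P; the floral
#' morph follows: thrum = short style + high anthers, pin = long + low,
#' short homostyle = short + low, long homostyle = long + high.
#' Homostyles are self-fertile (stigma and anthers at the same height).
#'
#' @param hap1,hap2 the two haplotypes of the individual
#' @param design the [cross_design()]
#' @return named character vector of per-locus phenotype labels
#'   ("mutant"/"wild_type", or the morph at the S locus), with
#'   attributes `pollen` ("large"/"small") and `self_fertile` when a
#'   composite S locus is present
#' @export
#' @examples
#' d <- design_okl_s_hih()
#' phenotype_of(c("okl", "GPA", "HIH"), c("okl", "gpa", "hih"), d)
phenotype_of <- function(hap1, hap2, design) {
  hap1 <- validate_haplotype(hap1, design)
  hap2 <- validate_haplotype(hap2, design)
  out <- character(length(design$loci))
  pollen <- NULL
  self_fertile <- NULL
  for (i in seq_along(design$loci)) {
    l <- design$loci[[i]]
    out[i] <- switch(
      l$dominance,
      mutant_dominant = if (hap1[i] == l$dominant || hap2[i] == l$dominant)
        "mutant" else "wild_type",
      mutant_recessive = if (hap1[i] == l$recessive && hap2[i] == l$recessive)
        "mutant" else "wild_type",
      composite_S = {
        tr <- s_traits(hap1[i], hap2[i])
        pollen <- if (tr$pollen_large) "large" else "small"
        m <- morph_from_traits(tr)
        self_fertile <- m %in% c("short_homostyle", "long_homostyle")
        m
      },
      stop_design("unknown dominance mode '", l$dominance, "'"))
  }
  names(out) <- design$locus_names
  attr(out, "pollen") <- pollen
  attr(out, "self_fertile") <- self_fertile
  out
}

#' Crossover categories of a three-locus heterozygote's gametes
#'
#' For a parent heterozygous at the three loci of `locus_order`, returns
#' the eight gamete haplotypes grouped into four reciprocal pairs:
#' `parental`, `single_interval_1` (crossover between loci 1 and 2),
#' `single_interval_2` (between loci 2 and 3) and `double`. Members of a
#' pair are allele-wise complements at the three loci.
#'
#' @param parent a [parent_genotype()] or parent id known to `design`
#' @param design the [cross_design()]; its locus order is used
#' @return named list mapping each category to a list of two haplotypes
#'   (character vectors in locus order)
#' @export
enumerate_gamete_classes <- function(parent, design) {
  parent <- get_parent(design, parent)
  h1 <- validate_haplotype(parent$hap1, design)
  h2 <- validate_haplotype(parent$hap2, design)
  if (length(h1) != 3)
    stop_design("three-point enumeration requires exactly 3 loci, got ",
                length(h1))
  hom <- which(h1 == h2)
  if (length(hom) > 0)
    stop_design("parent '", parent$id, "' is homozygous at locus ",
                paste(design$locus_names[hom], collapse = ", "),
                "; gamete classes are degenerate")
  # chromosome-of-origin patterns per category; second pattern is the
  # reciprocal complement
  patterns <- list(
    parental          = list(c(1, 1, 1), c(2, 2, 2)),
    single_interval_1 = list(c(1, 2, 2), c(2, 1, 1)),
    single_interval_2 = list(c(1, 1, 2), c(2, 2, 1)),
    double            = list(c(1, 2, 1), c(2, 1, 2)))
  haps <- rbind(h1, h2)
  lapply(patterns, function(pp)
    lapply(pp, function(o) vapply(1:3, function(i) haps[o[i], i], character(1))))
}

#' Expected progeny phenotype classes of a testcross
#'
#' Crosses every gamete class of the informative parent onto the tester
#' gamete and tabulates the resulting phenotype, one row per gamete.
#' This is the lookup used to assign observed progeny (or class-count
#' rows) to crossover categories.
#'
#' @param informative,tester parents (objects or ids known to `design`)
#' @param design the [cross_design()]
#' @return data.frame with columns `category`, `gamete` (1 or 2 within
#'   the reciprocal pair), one phenotype column per locus, and `pollen`
#' @export
phenotype_classes <- function(informative, tester, design) {
  informative <- get_parent(design, informative)
  tester <- get_parent(design, tester)
  if (tester$role != "tester" || any(tester$hap1 != tester$hap2))
    stop_design("tester parent must have role 'tester' and be homozygous")
  classes <- enumerate_gamete_classes(informative, design)
  rows <- list()
  for (cat in names(classes)) {
    for (g in 1:2) {
      ph <- phenotype_of(classes[[cat]][[g]], tester$hap1, design)
      rows[[length(rows) + 1]] <- c(list(category = cat, gamete = g),
                                    as.list(ph),
                                    list(pollen = attr(ph, "pollen") %||% NA_character_))
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Classify one progeny phenotype into a crossover category
#'
#' Finds the informative-parent gamete whose combination with the tester
#' gamete reproduces the observed phenotype, and returns its category.
#' Homostyle morphs are returned as `intra_S` (a recombination event
#' within the composite S locus). Entries equal to `"unscored"` are
#' ignored in the comparison; the individual can only be classified if
#' the scored entries identify a unique category.
#'
#' @param phenotype named character vector of per-locus labels (names =
#'   locus names; S locus entry is the morph)
#' @param informative,tester parents (objects or ids known to `design`)
#' @param design the [cross_design()]
#' @param individual_id optional id used in error messages
#' @return one of "parental", "single_interval_1", "single_interval_2",
#'   "double", "intra_S"
#' @export
classify_progeny <- function(phenotype, informative, tester, design,
                             individual_id = NULL) {
  s_idx <- which(vapply(design$loci, function(l) l$dominance == "composite_S",
                        logical(1)))
  if (length(s_idx) == 1) {
    morph <- phenotype[[design$locus_names[s_idx]]]
    if (!is.na(morph) && morph != "unscored" &&
        !morph %in% c("pin", "thrum"))
      return("intra_S")
  }
  tab <- phenotype_classes(informative, tester, design)
  ph <- phenotype[design$locus_names]
  keep <- design$locus_names[!is.na(ph) & ph != "unscored"]
  if (length(keep) == 0)
    stop_data("individual ", individual_id %||% "?", ": no scored loci")
  hit <- vapply(seq_len(nrow(tab)), function(i)
    all(unlist(tab[i, keep]) == phenotype[keep]), logical(1))
  cats <- unique(tab$category[hit])
  if (length(cats) == 0)
    stop_data("individual ", individual_id %||% "?",
              ": phenotype reproducible by no gamete class ",
              "(possible contaminant or selfing): ",
              paste(names(phenotype), phenotype, sep = "=", collapse = ", "))
  if (length(cats) > 1)
    stop_data("individual ", individual_id %||% "?",
              ": scored loci do not identify a unique crossover category")
  cats
}
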