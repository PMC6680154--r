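#' Configure a testcross simulation
#'
#' Progeny are drawn from the four three-locus gamete classes of the
#' informative parent with probabilities determined by the two interval
#' recombination fractions and the coefficient of coincidence:
#' P(double) = c*r1*r2, P(single_1) = r1 - c*r1*r2, P(single_2) =
#' r2 - c*r1*r2, P(parental) = 1 - r1 - r2 + c*r1*r2. Interference is
#' modelled through the single multiplier `c` so that the simulator's
#' parameter is identical to the estimator's output. Independently of
#' the flanking intervals, each meiosis recombines within the composite
#' S locus with probability `h`, producing homostyle progeny.
#'
#' @param design a [cross_design()] containing the two parents
#' @param informative,tester parent ids (or objects) within `design`
#' @param r1 recombination fraction in interval 1 (locus 1 to locus 2),
#'   in `[0, 0.5]`
#' @param r2 recombination fraction in interval 2 (locus 2 to locus 3)
#' @param c coefficient of coincidence (>= 0); 1 = no interference,
#'   0 = complete interference (no doubles)
#' @param h intra-S recombination probability per meiosis (default 0)
#' @param n progeny count
#' @param seed integer seed; all draws flow from this one stream
#' @return an object of class `slocus_sim_config`
#' @export
sim_config <- function(design, informative, tester, r1, r2, c = 1, h = 0,
                       n, seed = NULL) {
  stopifnot(r1 >= 0, r1 <= 0.5, r2 >= 0, r2 <= 0.5, c >= 0, h >= 0, h <= 1,
            n >= 1)
  gamete_class_probs(r1, r2, c)  # validates feasibility
  structure(list(design = design,
                 informative = get_parent(design, informative),
                 tester = get_parent(design, tester),
                 r1 = r1, r2 = r2, c = c, h = h, n = as.integer(n),
                 seed = seed),
            class = "slocus_sim_config")
}

#' Gamete class probabilities under coincidence c
#'
#' @inheritParams sim_config
#' @return named numeric vector over parental / single_interval_1 /
#'   single_interval_2 / double, summing to 1
#' @export
gamete_class_probs <- function(r1, r2, c = 1) {
  pd <- c * r1 * r2
  p <- c(parental = 1 - r1 - r2 + pd,
         single_interval_1 = r1 - pd,
         single_interval_2 = r2 - pd,
         double = pd)
  if (any(p < -1e-12)) {
    bound <- min(ifelse(r1 > 0, 1 / r2, Inf), ifelse(r2 > 0, 1 / r1, Inf))
    stop_design("infeasible coincidence: class probabilities ",
                paste(sprintf("%s=%.4g", names(p), p), collapse = ", "),
                "; with r1=", r1, ", r2=", r2,
                " feasibility requires c <= ", format(bound))
  }
  pmax(p, 0)
}

# chromosome-of-origin patterns per (category, gamete-within-pair)
origin_patterns <- function() {
  list(parental          = list(c(1L, 1L, 1L), c(2L, 2L, 2L)),
       single_interval_1 = list(c(1L, 2L, 2L), c(2L, 1L, 1L)),
       single_interval_2 = list(c(1L, 1L, 2L), c(2L, 2L, 1L)),
       double            = list(c(1L, 2L, 1L), c(2L, 1L, 2L)))
}

#' Draw gamete-class counts for one simulated cross
#'
#' One multinomial draw of size `n` over the four crossover categories,
#' with each category's count split binomially between its two
#' reciprocal gametes (meiotic sampling, not forced equality).
#'
#' @param config a [sim_config()]
#' @return list with `category` (named counts over the four categories)
#'   and `gamete` (4 x 2 matrix of counts per reciprocal gamete)
#' @export
simulate_gamete_counts <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- gamete_class_probs(config$r1, config$r2, config$c)
  counts <- as.integer(stats::rmultinom(1, config$n, p))
  names(counts) <- names(p)
  g1 <- stats::rbinom(4, counts, 0.5)
  gamete <- cbind(g1, counts - g1)
  dimnames(gamete) <- list(names(p), c("gamete_1", "gamete_2"))
  list(category = counts, gamete = gamete)
}

#' Simulate a full testcross progeny table
#'
#' Draws gamete classes, applies intra-S recombination with probability
#' `h` (crossover point uniform over the G-P and P-A sub-intervals), and
#' converts each gamete to a progeny phenotype against the tester
#' gamete. Both the observed phenotype and the true crossover category
#' are recorded so downstream estimators can be checked against truth.
#'
#' @param config a [sim_config()]
#' @return object of class `slocus_sim`: list with `individuals` (one
#'   row per progeny: id, chromosome origins per locus, true category,
#'   per-locus phenotype labels, pollen size), `class_counts`
#'   (aggregated per-phenotype-class counts), and `config`
#' @export
simulate_cross <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  design <- config$design
  inf <- config$informative
  p <- gamete_class_probs(config$r1, config$r2, config$c)
  counts <- as.integer(stats::rmultinom(1, config$n, p))
  pat <- origin_patterns()
  cats <- rep(names(p), counts)
  gsel <- stats::rbinom(config$n, 1, 0.5) + 1L
  # origins: n x 3 matrix of chromosome index per locus
  origins <- t(vapply(seq_len(config$n),
                      function(i) pat[[cats[i]]][[gsel[i]]], integer(3)))
  # shuffle so individual order is not grouped by category
  ord <- sample.int(config$n)
  cats <- cats[ord]; origins <- origins[ord, , drop = FALSE]

  haps <- rbind(validate_haplotype(inf$hap1, design),
                validate_haplotype(inf$hap2, design))
  gam <- vapply(1:3, function(j) haps[origins[, j], j],
                character(config$n))
  if (!is.matrix(gam)) gam <- matrix(gam, nrow = config$n)

  s_idx <- which(vapply(design$loci, function(l) l$dominance == "composite_S",
                        logical(1)))
  true_cat <- cats
  if (config$h > 0 && length(s_idx) == 1) {
    hit <- stats::runif(config$n) < config$h
    if (any(hit)) {
      brk <- sample(1:2, sum(hit), replace = TRUE)  # after G, or after P
      cur <- gam[hit, s_idx]
      other <- ifelse(origins[hit, s_idx] == 1L,
                      haps[2, s_idx], haps[1, s_idx])
      gam[hit, s_idx] <- paste0(substr(cur, 1, brk),
                                substr(other, brk + 1, 3))
      true_cat[hit] <- "intra_S"
    }
  }

  tester_hap <- validate_haplotype(config$tester$hap1, design)
  phen <- matrix(NA_character_, config$n, length(design$loci),
                 dimnames = list(NULL, design$locus_names))
  pollen <- rep(NA_character_, config$n)
  for (j in seq_along(design$loci)) {
    l <- design$loci[[j]]
    if (l$dominance == "mutant_dominant") {
      phen[, j] <- ifelse(gam[, j] == l$dominant | tester_hap[j] == l$dominant,
                          "mutant", "wild_type")
    } else if (l$dominance == "mutant_recessive") {
      phen[, j] <- ifelse(gam[, j] == l$recessive & tester_hap[j] == l$recessive,
                          "mutant", "wild_type")
    } else {
      short <- grepl("G", gam[, j]) | grepl("G", tester_hap[j])
      high <- grepl("A", gam[, j]) | grepl("A", tester_hap[j])
      large <- grepl("P", gam[, j]) | grepl("P", tester_hap[j])
      phen[, j] <- ifelse(short & high, "thrum",
                          ifelse(!short & !high, "pin",
                                 ifelse(short, "short_homostyle",
                                        "long_homostyle")))
      pollen <- ifelse(large, "large", "small")
    }
  }

  individuals <- data.frame(individual_id = seq_len(config$n),
                            origin_1 = origins[, 1], origin_2 = origins[, 2],
                            origin_3 = origins[, 3],
                            true_category = true_cat,
                            phen, pollen = pollen,
                            stringsAsFactors = FALSE, check.names = FALSE)
  class_counts <- stats::aggregate(
    list(count = rep(1L, config$n)),
    by = as.data.frame(phen, stringsAsFactors = FALSE), FUN = sum)
  structure(list(individuals = individuals, class_counts = class_counts,
                 config = config),
            class = "slocus_sim")
}

#' @export
print.slocus_sim <- function(x, ...) {
  cat("Simulated testcross:", x$config$n, "progeny, r1 =", x$config$r1,
      ", r2 =", x$config$r2, ", c =", x$config$c, ", h =", x$config$h, "\n")
  print(x$class_counts)
  invisible(x)
}

#' Simulate RFLP marker calls on simulated progeny
#'
#' The marker is heterozygous in the informative parent with its thrum
#' allele in coupling to the S haplotype. Each progeny's marker allele
#' travels with the chromosome segment that carried it: a marker distal
#' to a flanking locus cosegregates with that flank's chromosome of
#' origin; a marker inside a flank-S interval stays with the S side
#' unless that individual's crossover fell between the marker and S,
#' which happens with conditional probability `marker_r_to_S / r` given
#' a crossover in the interval.
#'
#' @param sim a [simulate_cross()] result
#' @param marker_id marker name
#' @param position one of "distal_to_flank1", "between_flank1_and_S",
#'   "between_S_and_flank2", "distal_to_flank2"
#' @param marker_r_to_S marker-to-S recombination fraction; must not
#'   exceed the containing interval's r for "between" positions
#' @return data.frame: individual_id, marker_id, allele_state
#'   ("thrum_pin_heterozygous" or "pin_only_homozygous"), plus the true
#'   chromosome of origin of the marker allele
#' @export
simulate_marker_calls <- function(sim, marker_id, position,
                                  marker_r_to_S = 0) {
  position <- match.arg(position, c("distal_to_flank1", "between_flank1_and_S",
                                    "between_S_and_flank2", "distal_to_flank2"))
  cfg <- sim$config
  ind <- sim$individuals
  design <- cfg$design
  haps <- rbind(validate_haplotype(cfg$informative$hap1, design),
                validate_haplotype(cfg$informative$hap2, design))
  s_idx <- which(vapply(design$loci, function(l) l$dominance == "composite_S",
                        logical(1)))
  if (length(s_idx) != 1)
    stop_design("marker simulation requires a composite S locus")
  thrum_chrom <- which(grepl("G", haps[, s_idx]))
  if (length(thrum_chrom) != 1)
    stop_design("informative parent must be heterozygous at the S locus")

  n <- nrow(ind)
  origin <- switch(position,
    distal_to_flank1 = ind$origin_1,
    distal_to_flank2 = ind$origin_3,
    between_flank1_and_S = {
      if (marker_r_to_S > cfg$r1)
        stop_design("marker_r_to_S exceeds interval 1 recombination fraction")
      co <- ind$origin_1 != ind$origin_2
      q <- if (cfg$r1 > 0) marker_r_to_S / cfg$r1 else 0
      flank_side <- co & (stats::runif(n) < q)
      ifelse(flank_side, ind$origin_1, ind$origin_2)
    },
    between_S_and_flank2 = {
      if (marker_r_to_S > cfg$r2)
        stop_design("marker_r_to_S exceeds interval 2 recombination fraction")
      co <- ind$origin_2 != ind$origin_3
      q <- if (cfg$r2 > 0) marker_r_to_S / cfg$r2 else 0
      flank_side <- co & (stats::runif(n) < q)
      ifelse(flank_side, ind$origin_3, ind$origin_2)
    })
  data.frame(individual_id = ind$individual_id,
             marker_id = marker_id,
             allele_state = ifelse(origin == thrum_chrom,
                                   "thrum_pin_heterozygous",
                                   "pin_only_homozygous"),
             true_origin = origin,
             stringsAsFactors = FALSE)
}
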