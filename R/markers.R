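#' Cosegregation verdict for one recombinant individual
#'
#' Compares a molecular marker's observed allele state in a
#' single-crossover recombinant against the expectation if the marker
#' stayed coupled to its S-locus-side allele. With the thrum marker
#' allele in coupling to the dominant S haplotype (the only phase the
#' placement logic supports), a thrum recombinant retaining
#' heterozygosity — or a pin recombinant homozygous for the pin allele —
#' shows the marker still travelling with S (`marker_with_S`); loss of
#' the S-coupled allele in a thrum, or gain of it in a pin, shows a
#' marker-S crossover (`marker_recombined_from_S`). Missing calls and
#' novel bands are `uninformative`; novel bands are flagged since they
#' may be either mutation or recombination.
#'
#' @param morph floral morph of the recombinant ("pin" or "thrum";
#'   homostyles are uninformative)
#' @param allele_state one of "pin_only_homozygous",
#'   "thrum_pin_heterozygous", "novel_band", "missing"
#' @param phase phase of the marker's thrum allele relative to S; must
#'   be "coupling" (supplying it is mandatory, to make the assumption
#'   explicit)
#' @return character verdict, with attribute `novel` TRUE for novel
#'   bands
#' @export
cosegregation_verdict <- function(morph, allele_state, phase) {
  if (missing(phase))
    stop_design("marker phase must be supplied ('coupling' = thrum allele ",
                "on the S haplotype)")
  if (!identical(phase, "coupling"))
    stop_design("only coupling phase (thrum allele on the S haplotype) is ",
                "supported; got '", phase, "'")
  allele_state <- match.arg(allele_state,
                            c("pin_only_homozygous", "thrum_pin_heterozygous",
                              "novel_band", "missing"))
  if (allele_state %in% c("novel_band", "missing")) {
    v <- "uninformative"
    attr(v, "novel") <- allele_state == "novel_band"
    return(v)
  }
  if (!morph %in% c("pin", "thrum")) {
    v <- "uninformative"
    attr(v, "novel") <- FALSE
    return(v)
  }
  expected_het <- morph == "thrum"  # S gamete carries the thrum allele
  observed_het <- allele_state == "thrum_pin_heterozygous"
  v <- if (expected_het == observed_het) "marker_with_S"
  else "marker_recombined_from_S"
  attr(v, "novel") <- FALSE
  v
}

#' Place a marker relative to the S locus from recombinant evidence
#'
#' Uses flank-S single-crossover recombinants: if every recombinant in a
#' flank's interval also recombined the marker, the marker lies distal
#' to that flank; if every one kept the marker with S, a distal position
#' is excluded; a mixture places the marker between that flank and S.
#' Evidence from the two flanks is combined and must be consistent.
#'
#' @param calls data.frame with one row per informative individual:
#'   columns `individual_id`, `crossover_interval` ("flank1_to_S" or
#'   "S_to_flank2"), `morph`, `allele_state`
#' @param marker_id marker name (used in messages and the result)
#' @param phase marker phase, see [cosegregation_verdict()]
#' @param flank1,flank2 display names of the two flanking loci
#' @return object of class `slocus_placement`: list with `marker_id`,
#'   `supported_position` ("between_flank1_and_S", "between_S_and_flank2",
#'   "distal_to_flank1", "distal_to_flank2" or "indeterminate"),
#'   `supported_if_novel_recombinant` (alternative reading treating
#'   novel bands as marker-S recombination, NA when no novel bands),
#'   `excluded_positions`, `evidence` (per-individual verdicts),
#'   `novel_individuals`, `conflict`
#' @export
place_marker <- function(calls, marker_id, phase, flank1 = "flank1",
                         flank2 = "flank2") {
  req <- c("individual_id", "crossover_interval", "morph", "allele_state")
  if (!all(req %in% names(calls)))
    stop_data("marker calls need columns: ", paste(req, collapse = ", "))
  if (nrow(calls) == 0) stop_data("empty verdict list for ", marker_id)
  dup <- duplicated(calls$individual_id)
  if (any(dup)) {
    # one call per (individual, marker); conflicting duplicates are a
    # data error, identical duplicates are collapsed
    for (id in unique(calls$individual_id[dup])) {
      sub <- calls[calls$individual_id == id, ]
      if (length(unique(sub$allele_state)) > 1)
        stop_data("individual ", id, ": conflicting calls for ", marker_id)
    }
    calls <- calls[!dup, ]
  }
  if ("dominant_band" %in% calls$allele_state)
    stop_data("marker ", marker_id, " is scored as band presence/absence ",
              "(dominant, RAPD-like); zygosity cannot be read from such ",
              "calls, so placement by segregation is refused")

  verdicts <- character(nrow(calls))
  novel <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    v <- cosegregation_verdict(calls$morph[i], calls$allele_state[i], phase)
    verdicts[i] <- v
    novel[i] <- isTRUE(attr(v, "novel"))
  }
  evidence <- cbind(calls[req], verdict = verdicts, novel = novel)

  assess <- function(treat_novel_as_recombined) {
    vv <- verdicts
    if (treat_novel_as_recombined) vv[novel] <- "marker_recombined_from_S"
    excluded <- character(0)
    supported <- character(0)
    for (side in 1:2) {
      iv <- c("flank1_to_S", "S_to_flank2")[side]
      sub <- vv[calls$crossover_interval == iv]
      n_with <- sum(sub == "marker_with_S")
      n_rec <- sum(sub == "marker_recombined_from_S")
      distal <- paste0("distal_to_flank", side)
      between <- if (side == 1) "between_flank1_and_S" else "between_S_and_flank2"
      if (n_with > 0) excluded <- c(excluded, distal)
      if (n_rec > 0 && n_with > 0) supported <- c(supported, between)
      else if (n_rec > 0 && n_with == 0) supported <- c(supported, distal)
    }
    list(excluded = excluded, supported = supported)
  }

  base <- assess(FALSE)
  conflict <- length(base$supported) > 1 ||
    any(base$supported %in% base$excluded)
  supported <- if (conflict || length(base$supported) == 0) "indeterminate"
  else base$supported

  alt <- NA_character_
  if (any(novel)) {
    a <- assess(TRUE)
    alt <- if (length(a$supported) == 1 && !a$supported %in% a$excluded)
      a$supported else "indeterminate"
  }

  structure(list(marker_id = marker_id, supported_position = supported,
                 supported_if_novel_recombinant = alt,
                 excluded_positions = base$excluded, evidence = evidence,
                 novel_individuals = calls$individual_id[novel],
                 conflict = conflict, flank1 = flank1, flank2 = flank2),
            class = "slocus_placement")
}

#' @export
print.slocus_placement <- function(x, ...) {
  pos_label <- function(p) switch(
    p,
    between_flank1_and_S = paste("between", x$flank1, "and S"),
    between_S_and_flank2 = paste("between S and", x$flank2),
    distal_to_flank1 = paste("distal to", x$flank1),
    distal_to_flank2 = paste("distal to", x$flank2),
    p)
  cat("Marker", x$marker_id, "placement:", pos_label(x$supported_position), "\n")
  if (length(x$excluded_positions))
    cat("  excluded:", paste(vapply(x$excluded_positions, pos_label, ""),
                             collapse = "; "), "\n")
  if (length(x$novel_individuals))
    cat("  novel bands (mutation or recombination) in:",
        paste(x$novel_individuals, collapse = ", "),
        "\n  if recombination:", pos_label(x$supported_if_novel_recombinant), "\n")
  invisible(x)
}

#' Marker-to-S map distance
#'
#' Same recombination-percentage arithmetic as [interval_distance()],
#' with the full screened progeny count as denominator (not just the
#' subset examined on blots). When the only marker-S event is a novel
#' band that could be mutation rather than recombination, the distance
#' is additionally reported as an at-most bound; both readings are
#' returned rather than silently choosing one.
#'
#' @param marker_recombinants marker-S recombination events observed
#' @param total_progeny full screened progeny count
#' @param novel TRUE when the event(s) rest on a novel band
#' @return an `slocus_interval`; with `novel` the `bound` field is NA
#'   (rendered "<=") and `cm_if_recombinant` carries the point value
#' @export
marker_distance <- function(marker_recombinants, total_progeny,
                            novel = FALSE) {
  if (marker_recombinants == 0) return(zero_recombinant_bound(total_progeny))
  est <- interval_distance(marker_recombinants, total_progeny,
                           convention = "marker")
  if (novel) {
    est$cm_if_recombinant <- est$cm
    est$bound <- NA  # "<=": upper bound if the novel band is a mutation
  }
  est
}
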