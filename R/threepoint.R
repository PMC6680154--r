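#' A single cross's progeny record
#'
#' Progeny may be supplied either as phenotype-class counts (`classes`:
#' a data.frame with one column per design locus holding phenotype
#' labels plus a `count` column) or as pre-tabulated interval
#' recombinant counts (`interval_counts`), the form in which published
#' linkage tables usually print them. Both may be present.
#'
#' @param cross_id cross identifier
#' @param female,male parent ids
#' @param informative id of the doubly/triply heterozygous parent whose
#'   meioses the progeny classes reveal
#' @param n declared progeny total
#' @param classes optional per-phenotype-class count table
#' @param interval_counts optional named numeric:
#'   `c(interval_1 = , interval_2 = , intra_S = )`, counts as tabulated
#' @param declared optional named numeric of distances (cM) as printed
#'   in the source table, used only for cross-checking reports
#' @return an object of class `slocus_cross`
#' @export
cross_record <- function(cross_id, female, male, informative, n,
                         classes = NULL, interval_counts = NULL,
                         declared = NULL) {
  n <- as.integer(n)
  cross_id <- as.character(cross_id)
  informative <- as.character(informative)
  if (!is.null(classes)) {
    if (!"count" %in% names(classes))
      stop_data("cross ", cross_id, ": classes table needs a 'count' column")
    if (sum(classes$count) != n)
      stop_data("cross ", cross_id, ": class counts sum to ",
                sum(classes$count), ", declared total is ", n)
  }
  structure(list(cross_id = cross_id, female = female, male = male,
                 informative = informative, n = n, classes = classes,
                 interval_counts = interval_counts, declared = declared),
            class = "slocus_cross")
}

#' Pool crosses by informative parent
#'
#' Recombination events are only visible in chromosomes from the
#' heterozygous (informative) parent, so crosses sharing that parent are
#' pooled regardless of whether it served as female or male; the
#' homozygous tester's meioses never change the progeny class.
#'
#' @param crosses list of [cross_record()]s sharing one cross design
#' @return list of pools (class `slocus_pool`), one per informative
#'   parent, with elementwise-summed class counts and interval counts
#' @export
pool_by_parent <- function(crosses) {
  inf <- vapply(crosses, function(x) x$informative, character(1))
  lapply(split(crosses, factor(inf, levels = unique(inf))), function(grp) {
    classes <- NULL
    have_cls <- !vapply(grp, function(x) is.null(x$classes), logical(1))
    if (all(have_cls)) {
      key <- setdiff(names(grp[[1]]$classes), "count")
      if (!all(vapply(grp, function(x)
        identical(setdiff(names(x$classes), "count"), key), logical(1))))
        stop_design("crosses in one pool use different phenotype columns; ",
                    "mixed designs cannot be pooled")
      all_cls <- do.call(rbind, lapply(grp, function(x) x$classes))
      classes <- stats::aggregate(all_cls["count"], by = all_cls[key], FUN = sum)
    } else if (any(have_cls)) {
      stop_design("cannot pool crosses where only some have class counts")
    }
    ic <- NULL
    have_ic <- !vapply(grp, function(x) is.null(x$interval_counts), logical(1))
    if (all(have_ic)) {
      ic_mat <- do.call(rbind, lapply(grp, function(x) x$interval_counts))
      ic <- colSums(ic_mat)
    }
    structure(list(informative = grp[[1]]$informative,
                   cross_ids = vapply(grp, function(x) x$cross_id, character(1)),
                   n = sum(vapply(grp, function(x) x$n, integer(1))),
                   classes = classes, interval_counts = ic),
              class = "slocus_pool")
  })
}

#' Construct a parent pool from tabulated totals
#'
#' Published linkage tables print pooled totals rows directly; this
#' builds the pool object those rows describe, without per-cross data.
#'
#' @param informative informative parent id
#' @param n pooled progeny total
#' @param interval_counts named numeric `c(interval_1=, interval_2=,
#'   intra_S=)`
#' @param cross_ids optional member cross ids
#' @return an `slocus_pool`
#' @export
as_pool <- function(informative, n, interval_counts, cross_ids = character(0)) {
  structure(list(informative = as.character(informative),
                 cross_ids = cross_ids, n = as.integer(n), classes = NULL,
                 interval_counts = interval_counts),
            class = "slocus_pool")
}

design_tester <- function(design) {
  for (p in design$parents) if (p$role == "tester") return(p)
  stop_design("design has no tester parent")
}

#' Crossover-category counts from phenotype-class counts
#'
#' Assigns every phenotype class of a cross or pool to its crossover
#' category by matching against the expected testcross classes, and sums
#' counts. Homostyle morphs are counted as `intra_S`.
#'
#' @param x a [cross_record()] or pool with a `classes` table
#' @param design the [cross_design()], containing the informative parent
#'   and a tester
#' @return named numeric over parental / single_interval_1 /
#'   single_interval_2 / double / intra_S
#' @export
category_counts <- function(x, design) {
  if (is.null(x$classes))
    stop_data("no phenotype-class counts available for ",
              x$informative %||% "record")
  tester <- design_tester(design)
  out <- c(parental = 0, single_interval_1 = 0, single_interval_2 = 0,
           double = 0, intra_S = 0)
  for (i in seq_len(nrow(x$classes))) {
    ph <- unlist(x$classes[i, design$locus_names])
    names(ph) <- design$locus_names
    cat_i <- classify_progeny(ph, x$informative, tester, design,
                              individual_id = paste0("class row ", i))
    out[cat_i] <- out[cat_i] + x$classes$count[i]
  }
  out
}

#' Interval recombinant counts under a counting convention
#'
#' `column_as_printed` uses pre-tabulated interval counts exactly as
#' given (the arithmetic of published tables, whose distance columns are
#' 100 * tabulated count / N); when a record carries only class counts,
#' the standard `singles_plus_doubles` tabulation (each double crossover
#' counts once in each interval) is derived from them. Homostyles are
#' excluded from both flanking intervals and reported separately.
#'
#' @param x a [cross_record()] or pool
#' @param design the [cross_design()]
#' @param convention "column_as_printed" or "singles_plus_doubles"
#' @return named numeric: interval_1, interval_2, intra_S, plus
#'   attribute `doubles` when derived from classes
#' @export
interval_recombinant_counts <- function(x, design,
                                        convention = c("column_as_printed",
                                                       "singles_plus_doubles")) {
  convention <- match.arg(convention)
  if (convention == "column_as_printed" && !is.null(x$interval_counts)) {
    ic <- x$interval_counts
    return(c(interval_1 = unname(ic["interval_1"]),
             interval_2 = unname(ic["interval_2"]),
             intra_S = unname(ic["intra_S"] %||% 0)))
  }
  cc <- category_counts(x, design)
  c(interval_1 = unname(cc["single_interval_1"] + cc["double"]),
    interval_2 = unname(cc["single_interval_2"] + cc["double"]),
    intra_S = unname(cc["intra_S"]))
}

#' Infer gene order from the rarest reciprocal progeny pair
#'
#' In a three-point testcross the double-crossover progeny form the
#' rarest reciprocal pair, and a double crossover exchanges only the
#' middle locus relative to a parental gamete. The order is therefore
#' the one under which the observed rarest non-parental pair is the
#' double-crossover pair. Ties for rarest set an ambiguity flag; if all
#' non-parental classes are empty the result is indeterminate.
#'
#' @param pool a pool or cross with class counts
#' @param design the [cross_design()]
#' @return object of class `slocus_order`: list with `order` (locus
#'   names, middle locus second), `middle`, `rarest_pair` (its category
#'   label under the design's declared order), `rarest_count`,
#'   `ambiguous`, `indeterminate`
#' @export
infer_order <- function(pool, design) {
  cc <- category_counts(pool, design)
  nonpar <- cc[c("single_interval_1", "single_interval_2", "double")]
  res <- list(order = design$locus_names, middle = design$locus_names[2],
              rarest_pair = NA_character_, rarest_count = NA_real_,
              ambiguous = FALSE, indeterminate = FALSE)
  if (all(nonpar == 0)) {
    res$indeterminate <- TRUE
    res$order <- rep(NA_character_, 3)
    res$middle <- NA_character_
    return(structure(res, class = "slocus_order"))
  }
  rare <- names(nonpar)[nonpar == min(nonpar)]
  res$rarest_count <- unname(min(nonpar))
  res$ambiguous <- length(rare) > 1
  if (res$ambiguous) {
    # a tie for rarest never yields an arbitrary order
    res$rarest_pair <- paste(rare, collapse = "|")
    res$order <- rep(NA_character_, 3)
    res$middle <- NA_character_
    return(structure(res, class = "slocus_order"))
  }
  res$rarest_pair <- rare
  # the rarest pair switches exactly one locus relative to the parental
  # pair; that locus is the middle one
  middle_idx <- switch(rare,
                       double = 2L, single_interval_1 = 1L,
                       single_interval_2 = 3L)
  res$middle <- design$locus_names[middle_idx]
  res$order <- switch(as.character(middle_idx),
                      "1" = design$locus_names[c(2, 1, 3)],
                      "2" = design$locus_names,
                      "3" = design$locus_names[c(1, 3, 2)])
  structure(res, class = "slocus_order")
}

#' @export
print.slocus_order <- function(x, ...) {
  if (x$indeterminate) cat("Gene order indeterminate (no recombinants)\n")
  else if (x$ambiguous) cat("Gene order ambiguous: tie for rarest pair (",
                            x$rarest_pair, ")\n")
  else cat("Inferred gene order:", paste(x$order, collapse = " - "), "\n")
  invisible(x)
}

#' Canonical orientation of a locus order
#'
#' Orders are reversal-invariant; the canonical form puts the
#' alphabetically smaller endpoint first so orders can be compared.
#'
#' @param order character vector of three locus names
#' @return the same order, possibly reversed
#' @export
canonical_order <- function(order) {
  if (!any(is.na(order)) && order[1] > order[3]) rev(order) else order
}

#' Map distance of one interval
#'
#' Distance in centimorgans is the simple recombination percentage
#' 100 * recombinants / total; no mapping-function correction is applied
#' (see [haldane_cm()] / [kosambi_cm()] for opt-in transforms).
#'
#' @param recombinant_count recombinants observed in the interval
#' @param total progeny examined
#' @param convention label recording which counting convention produced
#'   the count
#' @return object of class `slocus_interval`: list with `count`,
#'   `total`, `cm` (exact), `cm_printed` (half-up, 2 dp), `bound`
#'   (FALSE), `convention`
#' @export
interval_distance <- function(recombinant_count, total,
                              convention = "column_as_printed") {
  if (total <= 0) stop_data("total must be positive")
  if (recombinant_count < 0 || recombinant_count > total)
    stop_data("recombinant count must lie in [0, total]")
  cm <- 100 * recombinant_count / total
  structure(list(count = recombinant_count, total = total, cm = cm,
                 cm_printed = round_half_up(cm, 2), bound = FALSE,
                 convention = convention),
            class = "slocus_interval")
}

#' @export
print.slocus_interval <- function(x, ...) {
  cat(sprintf("%s/%d recombinants: %s cM\n", format(x$count), x$total,
              format_cm(x$cm, x$bound)))
  invisible(x)
}

#' Zero-recombinant upper bound on map distance
#'
#' When no recombinant is observed among `total` progeny, the
#' theoretical maximum map distance is that implied by one hypothetical
#' recombinant: < 100/total cM. Numerically identical to
#' [interval_distance()] at count 1, but flagged as an upper bound.
#'
#' @param total progeny examined with zero recombinants
#' @return an `slocus_interval` with `bound = TRUE` and `count = 0`
#' @export
zero_recombinant_bound <- function(total) {
  est <- interval_distance(1, total)
  est$count <- 0
  est$bound <- TRUE
  est
}

#' Distance attributed to recombination within the composite S locus
#'
#' Homostyle progeny arise from rare crossovers between the S-locus
#' sub-genes; their frequency gives a map distance across the supergene.
#'
#' @inheritParams interval_distance
#' @return an `slocus_interval` with convention "intra_S"
#' @export
exceptional_class_distance <- function(intra_S_count, total) {
  interval_distance(intra_S_count, total, convention = "intra_S")
}

#' Coefficient of coincidence and interference
#'
#' c = observed doubles / (r1 * r2 * N), with r the two interval
#' recombination fractions; interference I = 1 - c. c > 1 (negative I)
#' means more double crossovers than the product rule predicts.
#'
#' @param observed_doubles count of double-crossover progeny
#' @param est1,est2 [interval_distance()] results on the same total N
#' @return object of class `slocus_coincidence`: list with `observed`,
#'   `expected`, `c`, `interference`, `defined`
#' @export
coincidence <- function(observed_doubles, est1, est2) {
  if (est1$total != est2$total)
    stop_data("interval estimates come from different totals (",
              est1$total, " vs ", est2$total, ")")
  expected <- (est1$cm / 100) * (est2$cm / 100) * est1$total
  if (expected == 0)
    return(structure(list(observed = observed_doubles, expected = 0,
                          c = NA_real_, interference = NA_real_,
                          defined = FALSE),
                     class = "slocus_coincidence"))
  cc <- observed_doubles / expected
  structure(list(observed = observed_doubles, expected = expected,
                 c = cc, interference = 1 - cc, defined = TRUE),
            class = "slocus_coincidence")
}

#' @export
print.slocus_coincidence <- function(x, ...) {
  if (!x$defined) cat("Coincidence undefined (expected doubles = 0)\n")
  else cat(sprintf(
    "Coincidence c = %.1f (observed %g vs expected %.3g doubles), interference I = %.1f\n",
    x$c, x$observed, x$expected, x$interference))
  invisible(x)
}

#' Opt-in mapping-function transforms
#'
#' The package's distances are raw recombination percentages; these
#' standard transforms are provided for comparison only and are never
#' used in the reports.
#'
#' @param r recombination fraction (0 <= r < 0.5)
#' @return distance in cM under the Haldane or Kosambi mapping function
#' @export
haldane_cm <- function(r) -50 * log(1 - 2 * r)

#' @rdname haldane_cm
#' @export
kosambi_cm <- function(r) 25 * log((1 + 2 * r) / (1 - 2 * r))

#' Three-point analysis of a set of crosses
#'
#' The full pipeline over one cross design: pool crosses by informative
#' parent, infer gene order from the rarest reciprocal pair (where class
#' counts are available), estimate per-pool interval distances and the
#' intra-S (homostyle) distance, and assemble the combined row with
#' min-max ranges across pools. Zero-count intervals are reported as
#' zero-recombinant upper bounds. If declared (printed) distances were
#' attached to the pools' source table, computed values are checked
#' against them and mismatching cells are flagged as inconsistencies.
#'
#' @param crosses list of [cross_record()]s (may be NULL when `pools`
#'   is given)
#' @param design the [cross_design()]
#' @param convention counting convention, see
#'   [interval_recombinant_counts()]
#' @param declared optional data.frame of printed pool-level distances:
#'   columns `pool`, `interval` ("interval_1"/"interval_2"/"intra_S"),
#'   `cm`
#' @param pools optional list of tabulated pools ([as_pool()]); when a
#'   source table prints its own totals rows these take precedence for
#'   distance arithmetic, and any disagreement with the summed per-cross
#'   cells is flagged
#' @return object of class `slocus_threepoint`: list with `pools`
#'   (per-pool estimate table), `combined` (combined-row table with
#'   ranges), `order` (per-pool [infer_order()] results or NULL),
#'   `flags` (character vector of inconsistency annotations)
#' @export
analyze_threepoint <- function(crosses = NULL, design,
                               convention = c("column_as_printed",
                                              "singles_plus_doubles"),
                               declared = NULL, pools = NULL) {
  convention <- match.arg(convention)
  flags <- character(0)
  cross_pools <- if (!is.null(crosses)) pool_by_parent(crosses)
  if (is.null(pools)) {
    pools <- cross_pools
  } else if (!is.null(cross_pools)) {
    # tabulated totals rows are authoritative; check them against the
    # summed per-cross cells
    for (cp in cross_pools) {
      tp <- Filter(function(p) p$informative == cp$informative, pools)
      if (length(tp) != 1) next
      tp <- tp[[1]]
      if (tp$n != cp$n)
        flags <- c(flags, sprintf(
          "pool %s: tabulated total %d but member cross totals sum to %d",
          cp$informative, tp$n, cp$n))
      if (!is.null(cp$interval_counts)) {
        for (iv in names(tp$interval_counts)) {
          if (!iv %in% names(cp$interval_counts)) next
          if (tp$interval_counts[[iv]] != cp$interval_counts[[iv]])
            flags <- c(flags, sprintf(
              "pool %s %s: tabulated count %g but cross cells sum to %g",
              cp$informative, iv, tp$interval_counts[[iv]],
              cp$interval_counts[[iv]]))
        }
      }
    }
  }
  if (is.null(pools)) stop_data("supply crosses and/or pools")
  rows <- list()
  orders <- list()
  for (pool in pools) {
    ic <- interval_recombinant_counts(pool, design, convention)
    ests <- list(
      interval_1 = if (ic["interval_1"] > 0)
        interval_distance(ic["interval_1"], pool$n, convention)
      else zero_recombinant_bound(pool$n),
      interval_2 = if (ic["interval_2"] > 0)
        interval_distance(ic["interval_2"], pool$n, convention)
      else zero_recombinant_bound(pool$n),
      intra_S = exceptional_class_distance(ic["intra_S"], pool$n))
    if (!is.null(pool$classes))
      orders[[pool$informative]] <- infer_order(pool, design)
    for (iv in names(ests)) {
      e <- ests[[iv]]
      rows[[length(rows) + 1]] <- data.frame(
        pool = pool$informative, interval = iv, count = e$count,
        total = pool$n, cm = e$cm, cm_printed = e$cm_printed,
        bound = e$bound, stringsAsFactors = FALSE)
    }
  }
  pool_tab <- do.call(rbind, rows)

  # order inference needs class counts; fall back to the per-cross pools
  # when the tabulated totals rows carry none
  if (length(orders) == 0 && !is.null(cross_pools)) {
    for (cp in cross_pools)
      if (!is.null(cp$classes)) orders[[cp$informative]] <- infer_order(cp, design)
  }

  if (!is.null(declared)) {
    for (i in seq_len(nrow(declared))) {
      d <- declared[i, ]
      m <- pool_tab[pool_tab$pool == d$pool & pool_tab$interval == d$interval, ]
      if (nrow(m) == 1 && !m$bound && !isTRUE(all.equal(m$cm_printed, d$cm)))
        flags <- c(flags, sprintf(
          "pool %s %s: printed %.2f cM but tabulated count gives %d/%d = %.2f cM",
          d$pool, d$interval, d$cm, m$count, m$total, m$cm_printed))
    }
  }

  # the study-style order call pools all progeny of the design (the
  # informative parents share one phased genotype structure)
  order_combined <- NULL
  if (!is.null(crosses)) {
    with_cls <- Filter(function(x) !is.null(x$classes), crosses)
    if (length(with_cls) > 0) {
      all_cls <- do.call(rbind, lapply(with_cls, function(x) x$classes))
      key <- setdiff(names(all_cls), "count")
      comb_classes <- stats::aggregate(all_cls["count"], by = all_cls[key],
                                       FUN = sum)
      comb_rec <- list(informative = with_cls[[1]]$informative,
                       classes = comb_classes)
      order_combined <- infer_order(comb_rec, design)
    }
  }

  # order conflicts across pools (only unambiguous calls can conflict)
  ords <- Filter(function(o) !o$indeterminate && !o$ambiguous, orders)
  if (length(ords) > 1) {
    canon <- unique(lapply(ords, function(o) canonical_order(o$order)))
    if (length(canon) > 1)
      flags <- c(flags, paste0("conflicting gene orders across pools: ",
                               paste(vapply(canon, paste, "", collapse = "-"),
                                     collapse = " vs ")))
  }

  combined <- summarize_map(pool_tab, declared = declared)
  structure(list(pools = pool_tab, combined = combined, order = orders,
                 order_combined = order_combined, flags = flags,
                 convention = convention),
            class = "slocus_threepoint")
}

#' Combined map summary across parent pools
#'
#' Sums counts and totals over pools and reports, per interval, the
#' min-max range of the per-pool distances (collapsing to a point for a
#' single pool), alongside the combined-count distance. When declared
#' printed distances are supplied, an additional as-printed range is
#' reported from them.
#'
#' @param pool_tab per-pool estimate table as built by
#'   [analyze_threepoint()] (columns pool, interval, count, total, cm,
#'   cm_printed, bound)
#' @param declared optional printed distances (see
#'   [analyze_threepoint()])
#' @return data.frame with one row per interval: combined count, total,
#'   combined cM, computed range, and (if available) as-printed range
#' @export
summarize_map <- function(pool_tab, declared = NULL) {
  out <- list()
  for (iv in unique(pool_tab$interval)) {
    sub <- pool_tab[pool_tab$interval == iv, ]
    count <- sum(sub$count)
    total <- sum(sub$total)
    # a zero homostyle count is a plain 0.00 cM, not a bound
    comb <- if (count > 0) interval_distance(count, total)
    else if (iv == "intra_S") exceptional_class_distance(0, total)
    else zero_recombinant_bound(total)
    est_rows <- sub[!sub$bound, ]
    rng <- if (nrow(est_rows) > 0) range(est_rows$cm_printed) else c(NA, NA)
    range_str <- if (all(is.na(rng))) NA_character_
    else if (rng[1] == rng[2]) sprintf("%.2f", rng[1])
    else sprintf("%.2f-%.2f", rng[1], rng[2])
    printed_range <- NA_character_
    if (!is.null(declared)) {
      dsub <- declared[declared$interval == iv & !is.na(declared$cm), ]
      if (nrow(dsub) > 0) {
        drng <- range(dsub$cm)
        printed_range <- if (drng[1] == drng[2]) sprintf("%.2f", drng[1])
        else sprintf("%.2f-%.2f", drng[1], drng[2])
      }
    }
    out[[iv]] <- data.frame(interval = iv, count = count, total = total,
                            cm = comb$cm, cm_printed = comb$cm_printed,
                            bound = comb$bound, range = range_str,
                            printed_range = printed_range,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.slocus_threepoint <- function(x, ...) {
  cat("Three-point testcross analysis (convention:", x$convention, ")\n\n")
  print(x$pools, row.names = FALSE)
  cat("\nCombined:\n")
  print(x$combined, row.names = FALSE)
  if (!is.null(x$order_combined)) {
    cat("\nFrom pooled progeny: ")
    print(x$order_combined)
  }
  for (nm in names(x$order)) {
    cat("Pool ", nm, ": ", sep = "")
    print(x$order[[nm]])
  }
  if (length(x$flags)) {
    cat("\nFlags:\n")
    for (f in x$flags) cat(" !", f, "\n")
  }
  invisible(x)
}
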