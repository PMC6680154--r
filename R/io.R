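#' Read a cross design from a YAML config
#'
#' The config lists loci (name, dominance, allele symbols) in map order
#' and parents as two comma-separated haplotype strings plus a role,
#' e.g. `haplotype_1: "okl,GPA,HIH"`.
#'
#' @param path YAML file
#' @return a [cross_design()]
#' @export
read_cross_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$loci)) stop_data(path, ": config has no 'loci' section")
  loci <- lapply(cfg$loci, function(l)
    locus(l$name, l$dominance, l$dominant, l$recessive))
  parents <- lapply(cfg$parents %||% list(), function(p)
    parent_genotype(p$id, p$haplotype_1, p$haplotype_2, p$role))
  cross_design(loci, parents)
}

valid_labels <- function(l) {
  if (l$dominance == "composite_S")
    c("pin", "thrum", "short_homostyle", "long_homostyle", "unscored")
  else c("mutant", "wild_type", "unscored")
}

#' Read a progeny table into cross records
#'
#' Accepts three CSV layouts, detected from the header:
#' per-individual rows (`individual_id` plus one phenotype column per
#' locus), per-class count rows (`count` plus phenotype columns), or
#' table-layout interval counts (`interval_1`, `interval_2`, optional
#' `intra_S`, as printed in published linkage tables). All layouts need
#' `cross_id` and `informative`; `female`, `male` and `total` are
#' optional. Unknown phenotype labels are rejected with their line
#' numbers, and class counts that contradict a declared `total` are a
#' validation error.
#'
#' @param path CSV file
#' @param design the [cross_design()] naming the loci
#' @return list of [cross_record()]s
#' @export
read_progeny_table <- function(path, design) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop_data(path, ": empty progeny table")
  if (!all(c("cross_id", "informative") %in% names(df)))
    stop_data(path, ": needs 'cross_id' and 'informative' columns")
  df$cross_id <- as.character(df$cross_id)

  interval_form <- "interval_1" %in% names(df)
  if (!interval_form) {
    missing_loci <- setdiff(design$locus_names, names(df))
    if (length(missing_loci) > 0)
      stop_data(path, ": missing phenotype columns: ",
                paste(missing_loci, collapse = ", "))
    for (ln in design$locus_names) {
      ok <- valid_labels(design$loci[[ln]])
      bad <- which(!df[[ln]] %in% ok)
      if (length(bad) > 0)
        stop_data(path, ": unknown ", ln, " label '", df[[ln]][bad[1]],
                  "' at line ", bad[1] + 1)
    }
  }

  lapply(split(df, factor(df$cross_id, levels = unique(df$cross_id))),
         function(sub) {
    first <- sub[1, ]
    declared_n <- if ("total" %in% names(sub)) first$total else NA
    if (interval_form) {
      if (nrow(sub) != 1)
        stop_data(path, ": cross ", first$cross_id,
                  " has multiple interval-count rows")
      return(cross_record(
        first$cross_id, first$female %||% NA, first$male %||% NA,
        first$informative, declared_n,
        interval_counts = c(interval_1 = first$interval_1,
                            interval_2 = first$interval_2,
                            intra_S = if ("intra_S" %in% names(sub))
                              first$intra_S else 0)))
    }
    if ("count" %in% names(sub)) {
      classes <- sub[c(design$locus_names, "count")]
    } else if ("individual_id" %in% names(sub)) {
      classes <- stats::aggregate(
        list(count = rep(1L, nrow(sub))),
        by = sub[design$locus_names], FUN = sum)
    } else {
      stop_data(path, ": rows need either a 'count' or 'individual_id' column")
    }
    n <- if (!is.na(declared_n)) declared_n else sum(classes$count)
    cross_record(first$cross_id, first$female %||% NA, first$male %||% NA,
                 first$informative, n, classes = classes)
  })
}

#' Read a marker-call table
#'
#' @param path CSV with columns individual_id, crossover_interval,
#'   morph, marker_id, allele_state and optional bands
#' @return data.frame of calls
#' @export
read_marker_calls <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "crossover_interval", "morph", "marker_id",
           "allele_state")
  if (!all(req %in% names(df)))
    stop_data(path, ": needs columns ", paste(req, collapse = ", "))
  ok_iv <- c("flank1_to_S", "S_to_flank2")
  bad <- which(!df$crossover_interval %in% ok_iv)
  if (length(bad) > 0)
    stop_data(path, ": unknown crossover_interval '",
              df$crossover_interval[bad[1]], "' at line ", bad[1] + 1)
  df
}

#' Write a tab-separated report
#'
#' Writes a data.frame (or the tables of an [analyze_threepoint()]
#' result) as TSV with `#`-prefixed header comments echoing the run
#' configuration; flags become first-class annotation lines, not log
#' output. Output is deterministic: rerunning with the same inputs
#' yields a byte-identical file.
#'
#' @param x data.frame or `slocus_threepoint` object
#' @param path output file
#' @param header character vector of comment lines (e.g. seed, config)
#' @return `path`, invisibly
#' @export
write_report <- function(x, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  if (inherits(x, "slocus_threepoint")) {
    for (f in x$flags) writeLines(paste0("# FLAG: ", f), con)
    writeLines("# per-pool estimates", con)
    utils::write.table(format(x$pools, digits = 6), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines("# combined", con)
    utils::write.table(format(x$combined, digits = 6), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(format(as.data.frame(x), digits = 6), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write simulated progeny to CSV
#'
#' One row per individual with phenotype labels per locus; the true
#' crossover category is included unless `truth = FALSE`.
#'
#' @param sim a [simulate_cross()] result
#' @param path output CSV
#' @param cross_id,informative identifiers written into the table
#' @param truth include the true_category column
#' @return `path`, invisibly
#' @export
write_progeny_csv <- function(sim, path, cross_id = "sim",
                              informative = NULL, truth = TRUE) {
  design <- sim$config$design
  out <- data.frame(cross_id = cross_id,
                    informative = informative %||% sim$config$informative$id,
                    individual_id = sim$individuals$individual_id,
                    sim$individuals[design$locus_names],
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (truth) out$true_category <- sim$individuals$true_category
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
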