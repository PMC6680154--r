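#' Path to a packaged data file
#'
#' @param file file name under the package's `extdata/`
#' @return absolute path
#' @export
slocus_extdata <- function(file) {
  p <- system.file("extdata", file, package = "slocusmap", mustWork = FALSE)
  if (p == "") stop_data("no packaged file '", file, "'")
  p
}

#' Built-in cross designs
#'
#' `design_okl_s_hih()`: the Oakleaf - S - Hose in Hose testcross.
#' Thrum parents are heterozygous for the dominant Oakleaf (OKL) and
#' Hose in Hose (HIH) mutations with HIH in coupling and OKL in
#' repulsion to the dominant S haplotype; pin testers are homozygous
#' recessive throughout. Two informative thrum parents (Thrum-1,
#' Thrum-2, identical phased genotypes) and a representative tester are
#' registered.
#'
#' `design_okl_s_sep()`: the Oakleaf - S - sepaloid testcross. Thrum
#' parents carry OKL in coupling with S and the recessive sepaloid
#' allele in coupling with s; the tester is a sepaloid pin. Four
#' informative thrum parents (Thrum-1..Thrum-4) are registered.
#'
#' @return a [cross_design()]
#' @export
design_okl_s_hih <- function() {
  cross_design(
    list(locus("OKL", "mutant_dominant", "OKL", "okl"),
         locus("S", "composite_S"),
         locus("HIH", "mutant_dominant", "HIH", "hih")),
    list(parent_genotype("Thrum-1", c("okl", "GPA", "HIH"),
                         c("OKL", "gpa", "hih"), "informative"),
         parent_genotype("Thrum-2", c("okl", "GPA", "HIH"),
                         c("OKL", "gpa", "hih"), "informative"),
         parent_genotype("Pin-tester", c("okl", "gpa", "hih"),
                         c("okl", "gpa", "hih"), "tester")))
}

#' @rdname design_okl_s_hih
#' @export
design_okl_s_sep <- function() {
  loci <- list(locus("OKL", "mutant_dominant", "OKL", "okl"),
               locus("S", "composite_S"),
               locus("SEP", "mutant_recessive", "SEP", "sep"))
  thrums <- lapply(paste0("Thrum-", 1:4), function(id)
    parent_genotype(id, c("OKL", "GPA", "SEP"), c("okl", "gpa", "sep"),
                    "informative"))
  cross_design(loci, c(thrums, list(
    parent_genotype("Pin-sep", c("okl", "gpa", "sep"),
                    c("okl", "gpa", "sep"), "tester"))))
}

#' Packaged single-marker cosegregation survey
#'
#' F2 cosegregation counts for four S-linked molecular markers: plants
#' assayed, recombinants observed, and the published map distance (an
#' upper bound where zero recombinants were seen).
#'
#' @return data.frame with one row per marker
#' @export
table1_markers <- function() {
  utils::read.csv(slocus_extdata("table1_markers.csv"),
                  stringsAsFactors = FALSE)
}

#' Packaged three-point cross tables
#'
#' `table2_crosses()`: the six Oakleaf - S - Hose in Hose crosses (two
#' informative thrum parents, 2075 progeny) with tabulated per-interval
#' recombinant counts and, attached, a synthetic per-phenotype-class
#' reconstruction whose interval totals match the tabulated counts
#' (within-pair splits are not published; the double-crossover class
#' count is likewise unpublished and set to zero in the class table).
#'
#' `table3_crosses()`: the four Oakleaf - S - sepaloid crosses (601
#' progeny), with the class reconstruction that uniquely reconciles the
#' tabulated interval counts with the published pooled class counts
#' (6/2/1, single double crossover in cross 3) under the
#' singles-plus-doubles tabulation.
#'
#' @param classes attach the class-level reconstruction (default TRUE)
#' @return list of [cross_record()]s
#' @export
table2_crosses <- function(classes = TRUE) {
  design <- design_okl_s_hih()
  recs <- read_progeny_table(slocus_extdata("table2_crosses.csv"), design)
  if (classes) recs <- attach_classes(recs,
    slocus_extdata("fig2_classes_synthetic.csv"), design)
  recs
}

#' @rdname table2_crosses
#' @export
table3_crosses <- function(classes = TRUE) {
  design <- design_okl_s_sep()
  recs <- read_progeny_table(slocus_extdata("table3_crosses.csv"), design)
  if (classes) recs <- attach_classes(recs,
    slocus_extdata("fig3_classes_synthetic.csv"), design)
  recs
}

attach_classes <- function(recs, classes_path, design) {
  cls <- utils::read.csv(classes_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  cls$cross_id <- as.character(cls$cross_id)
  lapply(recs, function(r) {
    sub <- cls[cls$cross_id == r$cross_id, c(design$locus_names, "count")]
    if (nrow(sub) > 0) {
      if (sum(sub$count) != r$n)
        stop_data("cross ", r$cross_id, ": class reconstruction sums to ",
                  sum(sub$count), ", table total is ", r$n)
      r$classes <- sub
    }
    r
  })
}

#' Published pooled totals rows for the Hose in Hose cross
#'
#' The two "Totals" rows as printed (1291 and 784 progeny). These are
#' the authoritative inputs for the published distance arithmetic; note
#' that the printed per-cross cells do not quite sum to them (cross
#' totals 500+116+167 = 783, and thrum-1 S-HIH cells 2+0+3 = 5), which
#' [analyze_threepoint()] flags when both forms are supplied.
#'
#' @return list of pools ([as_pool()])
#' @export
table2_pools <- function() {
  df <- utils::read.csv(slocus_extdata("table2_pools.csv"),
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    as_pool(df$pool[i], df$total[i],
            c(interval_1 = df$interval_1[i], interval_2 = df$interval_2[i],
              intra_S = df$intra_S[i])))
}

#' Published pool-level distances for the Hose in Hose cross
#'
#' The printed per-pool distance cells, used to cross-check computed
#' values; the thrum-1 S-HIH cell (0.39 cM) disagrees with its own
#' tabulated count (6/1291 = 0.46) and is flagged by the analysis.
#'
#' @return data.frame with columns pool, interval, cm
#' @export
table2_declared <- function() {
  utils::read.csv(slocus_extdata("table2_pools_printed.csv"),
                  stringsAsFactors = FALSE)
}

#' Packaged RFLP calls on three-point-cross recombinants
#'
#' Allele calls for PvSLL1 and PvSLL2 on the twelve recombinant plants
#' shown in the blot figure: four S - Hose in Hose recombinants and
#' eight Oakleaf - S recombinants. Plant 6 carries a novel PvSLL1 band
#' (mutation or recombination, unresolved); plant 9 lacks the
#' S-coupled PvSLL2 allele (a marker-S recombination event). Plant 6's
#' morph is not stated in the source text and is set to pin; its
#' verdict is novel-band/uninformative either way.
#'
#' @return data.frame of marker calls
#' @export
fig4_marker_calls <- function() {
  read_marker_calls(slocus_extdata("fig4_marker_calls.csv"))
}

#' Packaged BAC sequence-group lengths
#'
#' Assembled sequence flanking the S locus, per BAC group: contig
#' counts and total kb (two groups anchored to the flanking contigs,
#' two unanchored pools).
#'
#' @return data.frame with columns group, contigs, kb, anchored
#' @export
contig_groups <- function() {
  utils::read.csv(slocus_extdata("contig_groups.csv"),
                  stringsAsFactors = FALSE)
}
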