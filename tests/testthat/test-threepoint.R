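# Pooling, gene order, distances, coincidence and the combined report.

test_that("crosses pool by informative parent with summed counts", {
  crosses <- table2_crosses()
  pools <- pool_by_parent(crosses)
  expect_named(pools, c("Thrum-1", "Thrum-2"))
  expect_equal(pools[["Thrum-1"]]$n, 413L + 430L + 448L)
  expect_equal(pools[["Thrum-1"]]$n, 1291L)
  expect_equal(unname(pools[["Thrum-1"]]$interval_counts["interval_1"]), 8)
  # the published thrum-2 totals row says 784; the printed cross totals
  # sum to 783 (an internal inconsistency of the source table, flagged
  # by analyze_threepoint when both forms are supplied)
  expect_equal(pools[["Thrum-2"]]$n, 783L)
  expect_equal(unname(pools[["Thrum-2"]]$interval_counts["interval_1"]), 20)

  single <- pool_by_parent(crosses[1])
  expect_equal(single[[1]]$n, crosses[[1]]$n)
  key <- function(df) sort(paste(df$OKL, df$S, df$HIH, df$count))
  expect_equal(key(single[[1]]$classes), key(crosses[[1]]$classes))

  # mixed designs cannot pool
  other <- cross_record("x", "f", "m", "Thrum-1", 10,
                        classes = data.frame(A = "mutant", S = "pin",
                                             B = "wild_type", count = 10))
  expect_error(pool_by_parent(list(crosses[[1]], other)), "mixed designs")
})

test_that("interval distances reproduce published table arithmetic", {
  expect_equal(interval_distance(8, 1291)$cm_printed, 0.62)
  expect_equal(interval_distance(20, 784)$cm_printed, 2.55)
  expect_equal(interval_distance(12, 784)$cm_printed, 1.53)
  expect_equal(interval_distance(6, 1291)$cm_printed, 0.46)
  expect_equal(interval_distance(1, 146)$cm_printed, 0.68)
  expect_equal(interval_distance(0, 100)$cm, 0)
  expect_error(interval_distance(1, 0), "positive")
  expect_error(interval_distance(5, 4), "\\[0, total\\]")
  # monotone in count at fixed total
  cms <- vapply(0:20, function(k) interval_distance(k, 100)$cm, numeric(1))
  expect_true(all(diff(cms) > 0))
})

test_that("zero-recombinant bounds equal the one-recombinant distance", {
  b <- zero_recombinant_bound(191)
  expect_equal(b$cm_printed, 0.52)
  expect_true(b$bound)
  expect_equal(format_cm(b$cm, b$bound), "<0.52")
  expect_equal(zero_recombinant_bound(1)$cm, 100)
  for (n in c(7, 61, 95, 146, 157, 174, 191, 500, 2075)) {
    expect_equal(zero_recombinant_bound(n)$cm, interval_distance(1, n)$cm)
  }
})

test_that("interval counting conventions differ by the double class", {
  d <- design_okl_s_hih()
  cfg <- sim_config(d, "Thrum-1", "Pin-tester", r1 = 0.1, r2 = 0.1, c = 1,
                    n = 2000, seed = 8)
  sim <- simulate_cross(cfg)
  rec <- cross_record("sim", "f", "m", "Thrum-1", 2000,
                      classes = sim$class_counts)
  cc <- category_counts(rec, d)
  spd <- interval_recombinant_counts(rec, d, "singles_plus_doubles")
  expect_equal(unname(spd["interval_1"]),
               unname(cc["single_interval_1"] + cc["double"]))
  # tabulated counts are used verbatim under column_as_printed
  rec2 <- cross_record("t", "f", "m", "Thrum-1", 100,
                       interval_counts = c(interval_1 = 7, interval_2 = 3,
                                           intra_S = 0))
  expect_equal(unname(
    interval_recombinant_counts(rec2, d, "column_as_printed")["interval_1"]),
    7)
})

test_that("category counts from classification equal simulator truth", {
  d <- design_okl_s_sep()
  cfg <- sim_config(d, "Thrum-1", "Pin-sep", r1 = 0.05, r2 = 0.02, c = 1,
                    h = 0, n = 3000, seed = 14)
  sim <- simulate_cross(cfg)
  rec <- cross_record("sim", "f", "m", "Thrum-1", 3000,
                      classes = sim$class_counts)
  cc <- category_counts(rec, d)
  truth <- table(sim$individuals$true_category)
  for (cat in names(truth)) {
    expect_equal(unname(cc[cat]), unname(as.numeric(truth[cat])))
  }
})

test_that("gene order comes from the rarest reciprocal pair", {
  # published pooled classes: 6 flank1-S singles, 2 flank2-S singles,
  # 1 double -> middle locus is S
  d3 <- design_okl_s_sep()
  cls <- data.frame(
    OKL = c("mutant", "wild_type", "mutant", "wild_type", "mutant",
            "wild_type", "mutant", "wild_type"),
    S = c("thrum", "pin", "pin", "thrum", "thrum", "pin", "pin", "thrum"),
    SEP = c("wild_type", "mutant", "mutant", "wild_type", "mutant",
            "wild_type", "wild_type", "mutant"),
    count = c(296, 296, 6, 0, 2, 0, 1, 0))
  rec <- cross_record("pooled", "f", "m", "Thrum-1", 601, classes = cls)
  ord <- infer_order(rec, d3)
  expect_equal(ord$order, c("OKL", "S", "SEP"))
  expect_equal(ord$middle, "S")
  expect_equal(ord$rarest_count, 1)
  expect_false(ord$ambiguous)

  # pooled Hose in Hose classes likewise put S in the middle
  d2 <- design_okl_s_hih()
  pools <- pool_by_parent(table2_crosses())
  for (p in pools) {
    o <- infer_order(p, d2)
    expect_equal(o$order, c("OKL", "S", "HIH"))
  }
})

test_that("order inference is invariant under locus relabelling", {
  # same biology declared in a different locus order: permute loci and
  # haplotypes consistently; the canonical inferred order must agree
  base <- list(c("OKL", "S", "SEP"), c(1, 2, 3))
  perms <- list(c(1, 2, 3), c(3, 2, 1), c(2, 1, 3), c(1, 3, 2))
  sim_counts <- c(parental = 290, single_interval_1 = 7,
                  single_interval_2 = 3, double = 1)
  ref <- NULL
  for (pm in perms) {
    loci <- list(locus("OKL", "mutant_dominant", "OKL", "okl"),
                 locus("S", "composite_S"),
                 locus("SEP", "mutant_recessive", "SEP", "sep"))[pm]
    h1 <- c("OKL", "GPA", "SEP")[pm]
    h2 <- c("okl", "gpa", "sep")[pm]
    tst <- c("okl", "gpa", "sep")[pm]
    d <- cross_design(loci, list(
      parent_genotype("inf", h1, h2, "informative"),
      parent_genotype("tst", tst, tst, "tester")))
    # counts defined against the *original* order's categories: build
    # classes from gametes so the biology is identical across perms
    cls_map <- enumerate_gamete_classes("inf", d)
    rows <- list()
    for (cat in names(cls_map)) {
      for (g in cls_map[[cat]]) {
        ph <- phenotype_of(g, tst, d)
        rows[[length(rows) + 1]] <- data.frame(
          t(ph[d$locus_names]),
          count = NA_integer_, category = cat)
      }
    }
    cls <- do.call(rbind, rows)
    # the category labels are relative to the declared order; map them
    # back to the original biology via the permutation of intervals:
    # only the identity of the *pair* matters, so assign counts by the
    # pair's gamete content instead
    okl_idx <- which(d$locus_names == "OKL")
    s_idx <- which(d$locus_names == "S")
    assign_count <- function(row) {
      # pairs identified by which loci separate from S
      okl_with_s <- (row[[which(names(row) == "OKL")]] == "mutant") ==
        (row[[which(names(row) == "S")]] == "thrum")
      sep_with_s <- (row[[which(names(row) == "SEP")]] == "wild_type") ==
        (row[[which(names(row) == "S")]] == "thrum")
      if (okl_with_s && sep_with_s) 290      # parental (OKL,GPA,SEP phase)
      else if (!okl_with_s && sep_with_s) 7  # OKL separated
      else if (okl_with_s && !sep_with_s) 3  # SEP separated
      else 1                                 # both separated: double
    }
    for (i in seq_len(nrow(cls))) cls$count[i] <- assign_count(cls[i, ])
    cls <- stats::aggregate(cls["count"], by = cls[d$locus_names],
                            FUN = function(x) x[1])
    rec <- cross_record("p", "f", "m", "inf", sum(cls$count), classes = cls)
    ord <- canonical_order(infer_order(rec, d)$order)
    if (is.null(ref)) ref <- ord
    expect_equal(ord, ref, info = paste(pm, collapse = ","))
  }
  expect_equal(ref, canonical_order(c("OKL", "S", "SEP")))
})

test_that("order ties and empty recombinant classes are reported, not guessed", {
  d <- design_okl_s_hih()
  tab <- phenotype_classes("Thrum-1", "Pin-tester", d)
  mk_classes <- function(counts_by_cat) {
    cls <- tab[, c(d$locus_names)]
    cls$count <- counts_by_cat[tab$category]
    cls
  }
  # single_interval_2 and double both empty: tie at the minimum
  tie <- cross_record("t", "f", "m", "Thrum-1", 204,
                      classes = mk_classes(c(parental = 100,
                                             single_interval_1 = 2,
                                             single_interval_2 = 0,
                                             double = 0)))
  ord <- infer_order(tie, d)
  expect_true(ord$ambiguous)
  expect_true(all(is.na(ord$order)))

  none <- cross_record("n", "f", "m", "Thrum-1", 200,
                       classes = mk_classes(c(parental = 100,
                                              single_interval_1 = 0,
                                              single_interval_2 = 0,
                                              double = 0)))
  ord2 <- infer_order(none, d)
  expect_true(ord2$indeterminate)
})

test_that("coincidence and interference follow the product-rule definition", {
  # I = 1 - c exactly, over assorted inputs
  for (case in list(c(4, 8, 6, 1291), c(3, 20, 12, 784), c(1, 5, 2, 299))) {
    e1 <- interval_distance(case[2], case[4])
    e2 <- interval_distance(case[3], case[4])
    cc <- coincidence(case[1], e1, e2)
    expect_equal(cc$interference, 1 - cc$c)
  }
  # observed equal to expectation: c = 1, I = 0
  e1 <- interval_distance(10, 1000); e2 <- interval_distance(20, 1000)
  cc <- coincidence(10 * 20 / 1000, e1, e2)
  expect_equal(cc$c, 1)
  expect_equal(cc$interference, 0)
  # direct arithmetic: 1 observed double, r1 = 5/299, r2 = 2/299
  cc2 <- coincidence(1, interval_distance(5, 299), interval_distance(2, 299))
  expect_equal(cc2$c, 299 / 10)
  # degenerate and invalid inputs
  expect_false(coincidence(0, interval_distance(0, 100),
                           interval_distance(5, 100))$defined)
  expect_error(coincidence(1, interval_distance(1, 100),
                           interval_distance(1, 200)),
               "different totals")
})

test_that("homostyle class distances use their own column", {
  expect_equal(exceptional_class_distance(1, 784)$cm_printed, 0.13)
  expect_equal(exceptional_class_distance(1, 2075)$cm_printed, 0.05)
  expect_equal(exceptional_class_distance(0, 1291)$cm, 0)
})

test_that("summarize_map collapses a single pool to a point range", {
  tab <- data.frame(pool = "p1",
                    interval = c("interval_1", "interval_2", "intra_S"),
                    count = c(5, 2, 0), total = 500,
                    cm = c(1, 0.4, 0), cm_printed = c(1, 0.4, 0),
                    bound = FALSE)
  sm <- summarize_map(tab)
  expect_equal(sm$range[sm$interval == "interval_1"], "1.00")
  expect_false(sm$bound[sm$interval == "intra_S"])
  expect_equal(sm$cm[sm$interval == "intra_S"], 0)
})

test_that("mapping-function transforms are consistent at small r", {
  # both approach 100r for small r and exceed it for larger r
  expect_equal(haldane_cm(0.001), 100 * 0.001, tolerance = 1e-2)
  expect_equal(kosambi_cm(0.001), 100 * 0.001, tolerance = 1e-2)
  expect_gt(haldane_cm(0.2), 20)
  expect_gt(haldane_cm(0.2), kosambi_cm(0.2))
})
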