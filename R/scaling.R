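#' Physical-to-genetic scaling of an anchored contig
#'
#' Relates a contig's physical length to the genetic distance it spans,
#' giving the local kb-per-cM relationship.
#'
#' @param contig_kb physical length in kb (> 0)
#' @param distance_cM genetic distance in cM (> 0); for a zero-distance
#'   interval use [separation_bound()] instead
#' @return object of class `slocus_scaling`: list with `contig_kb`,
#'   `distance_cM`, `kb_per_cM` (exact) and `kb_per_cM_printed`
#'   (half-up integer kb)
#' @export
kb_per_cm <- function(contig_kb, distance_cM) {
  if (contig_kb <= 0) stop_data("contig length must be positive")
  if (distance_cM <= 0)
    stop_data("distance must be positive; for zero-recombinant intervals ",
              "use separation_bound() on the physical lengths")
  ratio <- contig_kb / distance_cM
  structure(list(contig_kb = contig_kb, distance_cM = distance_cM,
                 kb_per_cM = ratio,
                 kb_per_cM_printed = round_half_up(ratio, 0)),
            class = "slocus_scaling")
}

#' @export
print.slocus_scaling <- function(x, ...) {
  cat(sprintf("%g kb over %g cM: %d kb/cM\n", x$contig_kb, x$distance_cM,
              as.integer(x$kb_per_cM_printed)))
  invisible(x)
}

#' kb-per-cM interval from a genetic distance range
#'
#' A fixed physical length over a range of genetic distances gives the
#' interval [contig_kb/high_cM, contig_kb/low_cM].
#'
#' @param contig_kb physical length in kb
#' @param distance_range numeric length-2 vector `(low_cM, high_cM)`,
#'   0 < low <= high
#' @return named numeric `c(low_kb_per_cM, high_kb_per_cM)` at printed
#'   integer precision, with attribute `exact` holding unrounded values
#' @export
range_scaling <- function(contig_kb, distance_range) {
  lo <- distance_range[1]; hi <- distance_range[2]
  if (lo <= 0) stop_data("distance range must be positive")
  if (lo > hi) stop_data("inverted distance range: low ", lo, " > high ", hi)
  exact <- c(low_kb_per_cM = contig_kb / hi, high_kb_per_cM = contig_kb / lo)
  out <- round_half_up(exact, 0)
  attr(out, "exact") <- exact
  out
}

#' Minimum physical separation spanned by anchored segments
#'
#' The sum of assembled segment lengths between two loci is a lower
#' bound on their physical separation (gaps only add to it).
#'
#' @param anchored_segments_kb non-empty numeric vector of non-negative
#'   segment lengths in kb
#' @return total kb, with attribute `Mb` rendered at 1 decimal
#' @export
separation_bound <- function(anchored_segments_kb) {
  if (length(anchored_segments_kb) == 0)
    stop_data("no anchored segments supplied")
  if (any(anchored_segments_kb < 0))
    stop_data("segment lengths must be non-negative")
  total <- sum(anchored_segments_kb)
  attr(total, "Mb") <- sprintf("%.1f Mb", round_half_up(total / 1000, 1))
  total
}
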