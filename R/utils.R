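#' Round half away from zero
#'
#' Map distances and kb/cM ratios are reported at the precision used in
#' classical linkage tables, which round halves up (5/299 = 1.6722 -> 1.67,
#' 888/0.39 = 2276.9 -> 2277). Base R's `round()` rounds halves to even, so
#' a dedicated helper is used everywhere a printed-precision number is made.
#'
#' @param x numeric vector
#' @param digits decimal places to keep (default 2)
#' @return numeric vector rounded half-up at `digits` places
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a centimorgan value for reports
#'
#' @param cm numeric distance in cM
#' @param bound logical; TRUE renders a "<" upper bound, NA renders a "≤"
#'   (at-most) bound used for hedged novel-band distances
#' @return character vector like "0.62", "<0.52" or "<=0.05"
#' @export
format_cm <- function(cm, bound = FALSE) {
  val <- sprintf("%.2f", round_half_up(cm, 2))
  prefix <- ifelse(is.na(bound), "<=", ifelse(bound, "<", ""))
  paste0(prefix, val)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_design <- function(...) {
  stop(structure(class = c("slocus_design_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("slocus_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
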