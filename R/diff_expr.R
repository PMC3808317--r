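#' Per-million normalization of a tag count
#'
#' Scales a raw count to reads-per-million of its library:
#' `count / total * 1e6`. Rounding happens only at presentation.
#'
#' @param count Non-negative read count(s).
#' @param total Positive library normalization denominator (total
#'   clean reads by default in this package).
#' @return Reads-per-million, unrounded.
#' @export
normalize_per_million <- function(count, total) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count / total * 1e6
}

#' Replace zero normalized expression with a small pseudo-value
#'
#' Zero reads-per-million values are replaced by `floor` (0.001 by
#' convention) so fold changes stay defined; positive values pass
#' through unchanged.
#'
#' @param norm Reads-per-million value(s).
#' @param floor Replacement for exact zeros.
#' @return Adjusted values, all `>= floor` or unchanged positives.
#' @export
pseudo_adjust <- function(norm, floor = 0.001) {
  if (any(norm < 0)) stop("normalized values must be >= 0")
  ifelse(norm == 0, floor, norm)
}

#' Log2 fold change between two pseudo-adjusted expression values
#'
#' @param norm_ref,norm_trt Pseudo-adjusted reads-per-million in the
#'   reference (control) and treated libraries.
#' @return `log2(norm_trt / norm_ref)`.
#' @export
log2_fold_change <- function(norm_ref, norm_trt) log2(norm_trt / norm_ref)

# log P(k | x) under the Audic-Claverie posterior with depth ratio r:
# P(k|x) = r^k (x+k)! / (x! k! (1+r)^{x+k+1})
ac_log_term <- function(k, x, r) {
  k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(r)
}

ac_pvalue_one <- function(x, y, n1, n2) {
  # condition on the library with the larger count (ties: larger depth)
  # so the test is invariant to the order of the two libraries
  if (x < y || (x == y && n1 < n2)) {
    tmp <- x; x <- y; y <- tmp
    tmp <- n1; n1 <- n2; n2 <- tmp
  }
  r <- n2 / n1
  # lower tail P(K <= y | x), terms evaluated in log space
  ks <- 0:y
  lower <- sum(exp(ac_log_term(ks, x, r)))
  upper <- 1 - lower + exp(ac_log_term(y, x, r))
  min(1, 2 * min(lower, upper))
}

#' Audic-Claverie significance of a count difference
#'
#' Exact test for a tag count difference between two sequencing
#' libraries of depths `n1` and `n2`. With \code{r = n2/n1} the posterior
#' probability of observing `k` counts in library 2 given `x` in
#' library 1 is `P(k|x) = r^k (x+k)! / (x! k! (1+r)^(x+k+1))`; the
#' two-sided p-value is twice the smaller of the two tails at the
#' observation `y` (both tails include `y`), capped at 1. Terms are
#' evaluated in log space so large counts stay finite. The test always
#' conditions on the library with the larger observed count (ties: the
#' deeper library), which makes the p-value exactly invariant to the
#' order in which the two libraries are given.
#'
#' @param x,y Observed counts in library 1 and 2 (vectors recycle).
#' @param n1,n2 Library depths (totals of clean reads).
#' @return Vector of two-sided p-values in `[0, 1]`.
#' @examples
#' audic_claverie_pvalue(5, 0, 1e6, 1e6)
#' @export
audic_claverie_pvalue <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library depths must be > 0")
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  vapply(seq_len(n), function(i) ac_pvalue_one(x[i], y[i], n1[i], n2[i]),
         numeric(1))
}

#' Classify the regulation direction of one expression record
#'
#' Up-regulated when the linear expression ratio exceeds `ratio_up`
#' with `p <= alpha`; down-regulated when the ratio is below
#' `ratio_down` with `p <= alpha`; otherwise not significant.
#'
#' @param ratio Linear treated/control ratio of pseudo-adjusted
#'   normalized expression.
#' @param pvalue Significance of the count difference.
#' @param ratio_up,ratio_down Ratio thresholds (defaults 2 and 0.5,
#'   i.e. |log2 fold change| > 1).
#' @param alpha Significance level.
#' @return Character vector over `{"up", "down", "ns"}`.
#' @export
classify_regulation <- function(ratio, pvalue, ratio_up = 2,
                                ratio_down = 0.5, alpha = 0.05) {
  dplyr::case_when(
    ratio > ratio_up & pvalue <= alpha ~ "up",
    ratio < ratio_down & pvalue <= alpha ~ "down",
    TRUE ~ "ns")
}

#' Differential expression of miRNAs between two libraries
#'
#' Normalizes per-library counts to reads-per-million, applies the
#' 0.001 pseudo-value to zeros, computes log2 fold changes
#' (treated/control), Audic-Claverie p-values and regulation calls.
#'
#' @param x Tibble with columns `id`, `count_ck` and `count_trt` (one
#'   row per miRNA).
#' @param total_ck,total_trt Normalization denominators: total clean
#'   reads of the control and treated libraries.
#' @param ratio_up,ratio_down,alpha Regulation-call thresholds, see
#'   [classify_regulation()].
#' @param fdr Apply a Benjamini-Hochberg correction and test the
#'   adjusted p-values instead? Off by default.
#' @param pseudo Replacement value for zero normalized expression.
#' @return A `mir_de` tibble: `id`, raw counts, pseudo-adjusted
#'   `norm_ck`/`norm_trt`, `log2fc`, `pvalue` (and `padj` if `fdr`),
#'   `regulation`, `significance` (`**` for p <= 0.01, `*` for p <=
#'   0.05). Use [tidy()] / [glance()] to extract results.
#' @export
mir_de <- function(x, total_ck, total_trt, ratio_up = 2, ratio_down = 0.5,
                   alpha = 0.05, fdr = FALSE, pseudo = 0.001) {
  x <- as_tibble(x)
  stopifnot(all(c("id", "count_ck", "count_trt") %in% names(x)))
  out <- x %>%
    mutate(norm_ck = pseudo_adjust(
             normalize_per_million(.data$count_ck, total_ck), pseudo),
           norm_trt = pseudo_adjust(
             normalize_per_million(.data$count_trt, total_trt), pseudo),
           log2fc = log2_fold_change(.data$norm_ck, .data$norm_trt),
           pvalue = audic_claverie_pvalue(.data$count_ck, .data$count_trt,
                                          total_ck, total_trt))
  ptest <- if (fdr) stats::p.adjust(out$pvalue, "BH") else out$pvalue
  if (fdr) out$padj <- ptest
  out <- out %>%
    mutate(regulation = classify_regulation(.data$norm_trt / .data$norm_ck,
                                            ptest, ratio_up, ratio_down,
                                            alpha),
           significance = dplyr::case_when(ptest <= 0.01 ~ "**",
                                           ptest <= 0.05 ~ "*",
                                           TRUE ~ ""))
  attr(out, "totals") <- c(ck = total_ck, trt = total_trt)
  attr(out, "thresholds") <- c(ratio_up = ratio_up, ratio_down = ratio_down,
                               alpha = alpha)
  class(out) <- c("mir_de", class(out))
  out
}

#' @rdname mir_de
#' @param x A `mir_de` object.
#' @param ... Unused.
#' @export
tidy.mir_de <- function(x, ...) {
  y <- x
  class(y) <- setdiff(class(y), "mir_de")
  as_tibble(y)
}

#' @rdname mir_de
#' @export
glance.mir_de <- function(x, ...) {
  th <- attr(x, "thresholds")
  tot <- attr(x, "totals")
  tibble(n = nrow(x),
         n_up = sum(x$regulation == "up"),
         n_down = sum(x$regulation == "down"),
         ratio_up = th[["ratio_up"]], ratio_down = th[["ratio_down"]],
         alpha = th[["alpha"]],
         total_ck = tot[["ck"]], total_trt = tot[["trt"]])
}

#' Volcano-style plot of a differential expression table
#'
#' @param object A `mir_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mir_de <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$pvalue, 1e-300)),
                               colour = .data$regulation)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#0570b0",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (treated/control)",
                  y = "-log10 p-value", colour = NULL) +
    ggplot2::theme_minimal()
}
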