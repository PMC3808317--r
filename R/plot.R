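#' Length distribution of small-RNA libraries
#'
#' Bar chart of the per-length read fractions of one or more tag
#' tables — the standard size-distribution figure of a small-RNA
#' study, where plant libraries peak at 21 and 24 nt.
#'
#' @param tags A tag table from [collapse_to_tags()] or a row-bound
#'   combination of several (the `library` column separates them).
#' @return A ggplot.
#' @export
plot_length_distribution <- function(tags) {
  d <- as_tibble(tags) %>%
    group_by(.data$library, .data$length) %>%
    summarise(reads = sum(.data$count), .groups = "drop_last") %>%
    mutate(fraction = .data$reads / sum(.data$reads)) %>%
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$length),
                                  y = .data$fraction,
                                  fill = .data$library)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "sequence length (nt)", y = "fraction of reads",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
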