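#' Heat-map of per-epoch co-occurrence sums
#'
#' Flat tile plot of the output of [cooccurrence_sums()]: category pairs on
#' the vertical axis, epochs on the horizontal, fill = co-occurrence sum.
#' Requires ggplot2.
#'
#' @param cooc Data frame from [cooccurrence_sums()].
#' @param drop_zero_pairs Hide pairs that never co-occur.
#' @return A ggplot object.
#' @export
plot_cooccurrence <- function(cooc, drop_zero_pairs = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_cooccurrence needs the ggplot2 package")
  cooc$pair <- paste(cooc$cat_a, cooc$cat_b, sep = " × ")
  if (drop_zero_pairs) {
    keep <- tapply(cooc$sum, cooc$pair, sum) > 0
    cooc <- cooc[cooc$pair %in% names(keep)[keep], , drop = FALSE]
  }
  ggplot2::ggplot(cooc, ggplot2::aes(x = epoch, y = pair, fill = sum)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "co-occurrence") +
    ggplot2::labs(x = "1-minute epoch", y = NULL) +
    ggplot2::theme_minimal()
}
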