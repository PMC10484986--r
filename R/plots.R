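#' Bar chart of the S/G mention split
#'
#' Proportion of studies in each S/G category, optionally faceted by
#' another label (e.g. `control_class` for the controlled/uncontrolled
#' panels).
#'
#' @param labels A labels tibble from [derive_labels()].
#' @param by Optional label column to facet by.
#' @return A ggplot object.
#' @export
plot_mention <- function(labels, by = NULL) {
  labels$sg_category <- factor(labels$sg_category,
                               c("analytical", "recruitment_only",
                                 "no_mention"))
  p <- ggplot2::ggplot(labels, ggplot2::aes(x = .data$sg_category)) +
    ggplot2::geom_bar(ggplot2::aes(y = ggplot2::after_stat(.data$prop),
                                   group = 1)) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "S/G mention", y = "Share of studies") +
    ggplot2::theme_minimal()
  if (!is.null(by)) p <- p + ggplot2::facet_wrap(by)
  p
}
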