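#' Plot a metagene profile
#'
#' Summit density over the length-normalised 5'UTR | CDS | 3'UTR axis, with
#' segment boundaries marked.
#'
#' @param profile A metagene tibble from [metagene()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  b <- nrow(profile) / 3
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = c(b, 2 * b) + 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_continuous(
      breaks = c(b / 2, 1.5 * b, 2.5 * b),
      labels = c("5'UTR", "CDS", "3'UTR")
    ) +
    ggplot2::labs(x = NULL, y = "summit density") +
    ggplot2::theme_classic()
}

#' @export
autoplot.ac4c_metagene <- function(object, ...) plot_metagene(object)

#' Plot cumulative fold-enrichment curves
#'
#' Empirical CDFs of transcript-level cumulative fold enrichment for several
#' groups, the package's analogue of the published cumulative distribution
#' panels.
#'
#' @param fe_list Named list of numeric fold-enrichment vectors (one per
#'   group).
#' @return A ggplot object.
#' @export
plot_cumulative_fe <- function(fe_list) {
  stopifnot(is.list(fe_list), !is.null(names(fe_list)))
  df <- purrr::imap_dfr(fe_list, function(x, nm) {
    dplyr::mutate(cumulative_curve(x), group = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$cdf,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::labs(x = "FE of ac4C", y = "cumulative fraction",
                  colour = NULL) +
    ggplot2::theme_classic()
}

#' @export
autoplot.motif_result <- function(object, ...) {
  df <- dplyr::mutate(object,
                      kmer = stats::reorder(.data$kmer, -.data$qvalue))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(pmax(.data$qvalue, 1e-300)),
                                   y = .data$kmer)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(-log[10] ~ "q"), y = NULL) +
    ggplot2::theme_classic()
}
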