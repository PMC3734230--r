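# ggplot2 helpers for the main result types.

#' Plot the repeat landscape
#' @param landscape Output of [tabulate_landscape()].
#' @param what `"n_families"`, `"total_bp"` or `"coverage_pct"`.
#' @return A ggplot.
#' @export
plot_repeat_landscape <- function(landscape, what = "n_families") {
  landscape$size_class <- factor(landscape$size_class,
                                 levels = landscape$size_class)
  ggplot2::ggplot(landscape,
                  ggplot2::aes(x = .data$size_class, y = .data[[what]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "repeat size class (bp)", y = what) +
    ggplot2::theme_minimal()
}

#' Plot a shared-sequence (or synteny) matrix as a heatmap
#' @param m A numeric matrix with dimnames.
#' @param trans Optional transform for the fill scale (e.g. "log10").
#' @return A ggplot.
#' @export
plot_matrix_heatmap <- function(m, trans = "identity") {
  df <- as_tibble(as.table(m), .name_repair = ~c("query", "subject", "value"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$query,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a tRNA distribution grid
#'
#' Species by tRNA tiles colored native / chloroplast-like / absent, the
#' usual census-figure layout.
#'
#' @param dist Long-form tibble from [build_trna_distribution()].
#' @return A ggplot.
#' @export
plot_trna_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$trna, y = .data$species,
                                     fill = .data$state)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(native = "gold",
                                          cp_like = "forestgreen",
                                          absent = "white")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
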