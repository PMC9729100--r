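#' Tidiers for crisprselect objects
#'
#' broom-style `tidy()` and `glance()` methods: `tidy()` returns the
#' rule-by-rule report of a cassette, the per-point summary of a selection
#' result, or the conditional table of a zygosity table; `glance()` returns a
#' one-row overview.
#'
#' @param x A `cassette`, `selection_result` or `zygosity_table`.
#' @param ... Unused.
#' @name tidy-crisprselect
NULL

#' Plot an editing profile
#'
#' Bar chart of allele-category frequencies in a sample.
#'
#' @param object An `editing_profile` from [quantify_sample()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.editing_profile <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[d$category != "DISCARDED", , drop = FALSE]
  d$category <- factor(d$category, levels = allele_categories())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(title = attr(object, "sample_id"),
                  x = NULL, y = "frequency of retained reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a selection result
#'
#' Per-replicate normalized variant:WT-prime fold changes by assay point,
#' with the frameshift control alongside; the dashed line at 1 is the
#' no-selection expectation.
#'
#' @param object A `selection_result` from [summarise_selection()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selection_result <- function(object, ...) {
  norm <- attr(object, "norm")
  pc <- attr(object, "point_col") %||% "point"
  d <- tidyr::pivot_longer(
    as_tibble(norm)[, c(pc, "fold", "fold_frameshift")],
    c("fold", "fold_frameshift"),
    names_to = "series", values_to = "value")
  d$series <- ifelse(d$series == "fold", "variant:WT'", "frameshift:WT'")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data[[pc]]), y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          linewidth = 0.3) +
    ggplot2::labs(x = "assay point", y = "fold change vs baseline",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a zygosity table
#'
#' Tile plot of unordered biallelic genotype counts.
#'
#' @param object A `zygosity_table` from [tabulate_zygosity()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zygosity_table <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$allele_a, y = .data$allele_b,
                               fill = .data$cells)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$cells), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("biallelic outcomes (%d cells)",
                                  object$n_cells)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
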