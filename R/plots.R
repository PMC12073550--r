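#' Plot methods for selection and stability results
#'
#' `autoplot()` methods give the standard diagnostic figures: ranked index
#' dot plots with the selection cutoff for `mgidi_result` / `mtsi_result`,
#' a WAASB bar ranking for `waasb_result`, and a loading heat map for
#' `factor_model`. `plot_differentials()` draws the per-site, per-trait
#' selection differentials.
#'
#' @param object Result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name metsel-plots
NULL

rank_index_plot <- function(index, value_col, intensity, title) {
  idx <- dplyr::arrange(index, dplyr::desc(.data[[value_col]]))
  idx$genotype <- factor(idx$genotype, levels = idx$genotype)
  cutoff <- max(idx[[value_col]][idx$selected])
  ggplot2::ggplot(idx, ggplot2::aes(
    x = .data$genotype, y = .data[[value_col]], colour = .data$selected)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 2, colour = "red") +
    ggplot2::coord_flip() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#1b7837")) +
    ggplot2::labs(
      title = title,
      subtitle = sprintf("%d of %d selected at %.0f%% intensity (lower = closer to the ideotype)",
                         sum(idx$selected), nrow(idx), intensity),
      x = NULL, y = toupper(value_col), colour = "selected") +
    ggplot2::theme_minimal()
}

#' @rdname metsel-plots
#' @export
autoplot.mgidi_result <- function(object, ...) {
  rank_index_plot(object$index, "mgidi", object$intensity,
                  "Genotype-ideotype distance ranking")
}

#' @rdname metsel-plots
#' @export
autoplot.mtsi_result <- function(object, ...) {
  rank_index_plot(object$index, "mtsi", object$intensity,
                  "Multi-trait stability ranking")
}

#' @rdname metsel-plots
#' @export
autoplot.waasb_result <- function(object, ...) {
  w <- dplyr::arrange(object$waasb, .data$waasb)
  w$genotype <- factor(w$genotype, levels = w$genotype)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$genotype, y = .data$waasb)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(title = "WAASB stability (lower = more stable)",
                  x = NULL, y = "WAASB") +
    ggplot2::theme_minimal()
}

#' @rdname metsel-plots
#' @export
autoplot.factor_model <- function(object, ...) {
  ld <- tidy(object) |>
    tidyr::pivot_longer(dplyr::starts_with("FA"), names_to = "factor",
                        values_to = "loading")
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$factor, y = .data$trait,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(title = "Rotated factor loadings", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname metsel-plots
#' @param differentials Tibble from [selection_differentials()].
#' @export
plot_differentials <- function(differentials) {
  ggplot2::ggplot(differentials, ggplot2::aes(
    x = .data$site, y = .data$differential, fill = .data$trait)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(title = "Selection differentials",
                  y = "differential (% of site mean)", x = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
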