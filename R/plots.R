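#' Plot a background distribution with an individual's score
#'
#' Histogram of the background raw scores with an optional vertical marker
#' for a tested individual and its percentile annotation.
#'
#' @param object a `prs_background`.
#' @param score optional raw score of a tested individual.
#' @param bins histogram bin count.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.prs_background <- function(object, score = NULL, bins = 30, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$raw_score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::labs(
      title = paste0(object$phenotype_id, " - ", object$population_label,
                     " background (n = ", object$n, ")"),
      x = "raw PRS", y = "samples"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(score)) {
    pct <- round_half_up(percentile_of(score, object), 2)
    p <- p +
      ggplot2::geom_vline(xintercept = score, colour = "firebrick",
                          linewidth = 0.8) +
      ggplot2::annotate("text", x = score, y = Inf, vjust = 1.5, hjust = -0.05,
                        label = paste0("percentile ", pct),
                        colour = "firebrick", size = 3.2)
  }
  p
}

#' Percentile grid across samples, phenotypes and backgrounds
#'
#' Tile plot of percentile placements: samples x phenotypes, faceted by
#' background population, coloured by percentile with the extreme-tail
#' entries labelled.
#'
#' @param assignments tibble from [assign_percentiles()].
#' @return a ggplot object.
#' @export
plot_percentile_grid <- function(assignments) {
  df <- assignments |>
    mutate(label = format(round_half_up(.data$percentile, 1), nsmall = 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                   y = .data$phenotype_id,
                                   fill = .data$percentile)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "seagreen", mid = "grey95",
                                  high = "firebrick", midpoint = 50,
                                  limits = c(0, 100)) +
    ggplot2::facet_wrap(~population_label) +
    ggplot2::labs(x = NULL, y = NULL, fill = "percentile") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Family percentiles with mid-parent expectation
#'
#' Dot plot of father/mother/child percentiles per phenotype with a marker
#' at the mid-parent value, highlighting the high-risk region above the
#' 80th percentile.
#'
#' @param family tibble from [family_report()].
#' @return a ggplot object.
#' @export
plot_family_percentiles <- function(family) {
  long <- family |>
    tidyr::pivot_longer(
      c("father_percentile", "mother_percentile", "child_percentile"),
      names_to = "member", values_to = "percentile"
    ) |>
    mutate(member = sub("_percentile$", "", .data$member))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$percentile,
                                     y = .data$phenotype_id)) +
    ggplot2::annotate("rect", xmin = 80, xmax = 100, ymin = -Inf, ymax = Inf,
                      alpha = 0.08, fill = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$member), size = 2.4) +
    ggplot2::geom_point(ggplot2::aes(x = .data$midparent), shape = 3,
                        colour = "grey40") +
    ggplot2::scale_x_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "percentile (primary background)", y = NULL,
                  colour = NULL,
                  caption = "+ mid-parent value; shaded: high-risk (>80th)") +
    ggplot2::theme_minimal()
}
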