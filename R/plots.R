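# ---- ggplot2 displays -------------------------------------------------------

#' Dot plot of organ-scale metrics by genotype
#'
#' One panel per metric with a point per animal (or per ventricle lobe for
#' lobe-level metrics) and the group mean as a crossbar — the standard
#' small-cohort display for descriptive morphometrics.
#'
#' @param records Morphometric records ([analyze_sample()] rows).
#' @return A ggplot object.
#' @export
plot_group_dots <- function(records) {
  long <- records |>
    dplyr::select("genotype", dplyr::where(is.numeric)) |>
    tidyr::pivot_longer(-"genotype", names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(metric = sub("_(left|right)$", "", .data$metric))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genotype, y = .data$value,
                                     colour = .data$genotype)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2, alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "black") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.lattice_stats <- function(object, ...) {
  ggplot2::ggplot(object$neighbour_frequencies,
                  ggplot2::aes(x = factor(.data$n), y = .data$frequency)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "neighbour number n", y = "frequency of cells",
                  title = paste0("apical neighbour distribution (",
                                 object$n_cells_interior,
                                 " interior cells, mean n = ",
                                 round(object$mean_neighbour_number, 2),
                                 ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.law_fit <- function(object, ...) {
  lew <- dplyr::mutate(object$lewis, law = "Lewis: A_n / A vs n")
  abo <- dplyr::mutate(object$aboav, law = "Aboav-Weaire: n m(n) vs n",
                       observed = .data$observed_nm,
                       expected = .data$expected_nm)
  d <- dplyr::bind_rows(lew[c("n", "observed", "expected", "law")],
                        abo[c("n", "observed", "expected", "law")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected),
                       colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        colour = "firebrick", size = 2) +
    ggplot2::facet_wrap(~law, scales = "free_y") +
    ggplot2::labs(x = "neighbour number n", y = NULL,
                  subtitle = "points: observed class means; line: law") +
    ggplot2::theme_minimal()
}

#' Histogram of per-cell ellipse-fit aspect ratios
#'
#' @param stats A [interior_stats()] result.
#' @param binwidth Histogram bin width (default 0.05).
#' @return A ggplot object.
#' @export
plot_aspect_ratios <- function(stats, binwidth = 0.05) {
  ggplot2::ggplot(stats$cells,
                  ggplot2::aes(x = .data$aspect_ratio)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35") +
    ggplot2::labs(x = "aspect ratio (major / minor axis)",
                  y = "cells") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
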