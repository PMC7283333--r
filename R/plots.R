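#' Plot a mean spatial-distance matrix
#'
#' @param object a `distance_matrix`.
#' @param ... unused.
#' @return A ggplot heat map (nm).
#' @export
autoplot.distance_matrix <- function(object, ...) {
  df <- tidy(object)
  df2 <- df
  names(df2)[1:2] <- c("region_j", "region_i")
  df <- dplyr::bind_rows(df, df2[, names(df)])
  ggplot2::ggplot(df, ggplot2::aes(.data$region_i, .data$region_j,
                                   fill = .data$mean_nm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "magma", direction = -1,
                                  name = "mean\ndistance (nm)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "region", y = "region") +
    ggplot2::theme_minimal()
}

#' Plot compartment scores along the chromosome
#'
#' @param object a `compartment_result`.
#' @param ... unused.
#' @return A ggplot bar chart, A regions above zero and B regions below.
#' @export
autoplot.compartment_result <- function(object, ...) {
  df <- tidy(object)
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$score,
                                   fill = .data$compartment)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(A = "#c0392b", B = "#2980b9")) +
    ggplot2::labs(x = "region", y = "compartment score") +
    ggplot2::theme_minimal()
}

#' Plot observed versus control polarization indices of an ensemble
#'
#' @param object a `polymer_ensemble`.
#' @param ... unused.
#' @return A ggplot box/jitter plot.
#' @export
autoplot.polymer_ensemble <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$pi)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "polarization index") +
    ggplot2::theme_minimal()
}

#' Plot chromosome-surface ratio against compartment score
#'
#' @param surface tibble with `score`, `surface_ratio` and `compartment`
#'   (e.g. the `surface` element of a `polymer_ensemble`, or measured
#'   per-region values).
#' @return A ggplot scatter with per-compartment linear fits.
#' @export
plot_surface_vs_score <- function(surface) {
  ggplot2::ggplot(surface, ggplot2::aes(.data$score, .data$surface_ratio,
                                        colour = .data$compartment)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(A = "#c0392b", B = "#2980b9")) +
    ggplot2::labs(x = "compartment score", y = "chromosome surface ratio") +
    ggplot2::theme_minimal()
}
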