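# Convenience figures for the main result types.

#' BIC/AIC curve over the K grid, with the first-plateau selection marked
#'
#' @param object A `gmm_grid` from [fit_gmm_grid()].
#' @param plateau_frac Plateau threshold passed to [select_K()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gmm_grid <- function(object, plateau_frac = 0.05, ...) {
  K_star <- suppressWarnings(as.integer(select_K(object, plateau_frac)))
  df <- object$criteria |>
    tidyr::pivot_longer(c("bic", "aic"), names_to = "criterion",
                        values_to = "value") |>
    dplyr::mutate(criterion = toupper(.data$criterion))
  ggplot2::ggplot(df, ggplot2::aes(.data$K, .data$value,
                                   colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = K_star, linetype = "dashed") +
    ggplot2::labs(
      x = "Number of clusters K", y = "Criterion (higher is better)",
      colour = NULL,
      subtitle = sprintf("First BIC plateau at K = %d", K_star)
    ) +
    ggplot2::theme_minimal()
}

#' Cluster transition diagram (trial n vs. trial n + 1)
#'
#' Heatmap of transition counts on a log scale, the standard rendering of
#' between-trial cluster transitions.
#'
#' @param object A `transition_matrix` from [transition_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame.table(unclass(object),
                                              stringsAsFactors = FALSE),
                          .name_repair = "minimal") |>
    setNames(c("from", "to", "count")) |>
    dplyr::mutate(
      from = as.integer(.data$from), to = as.integer(.data$to),
      count = ifelse(.data$count == 0, NA, .data$count)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10", na.value = "grey95") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Cluster at trial n", y = "Cluster at trial n + 1",
                  fill = "Transitions") +
    ggplot2::theme_minimal()
}

#' Cumulative exploration/exploitation curves of a session
#'
#' @param labels Per-trial cluster labels.
#' @return A ggplot object showing both running totals over trials.
#' @export
plot_cumulative_curves <- function(labels) {
  cumulative_curves(labels) |>
    tidyr::pivot_longer(c("n_explore_cum", "n_exploit_cum"),
                        names_to = "mode", values_to = "count") |>
    dplyr::mutate(mode = ifelse(.data$mode == "n_explore_cum",
                                "exploration", "exploitation")) |>
    ggplot2::ggplot(ggplot2::aes(.data$trial, .data$count,
                                 colour = .data$mode)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Trial", y = "Cumulative transitions", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Distribution of the true-vs-estimated EER mismatch across replicates
#'
#' A validation-study diagnostic: a distribution of differences centred on
#' zero indicates that EER computed from emergent clusters matches the
#' ground truth.
#'
#' @param cases A list of `validation_case` objects (or one).
#' @return A ggplot object, facetted by case.
#' @export
plot_validation_diff <- function(cases) {
  if (inherits(cases, "validation_case")) cases <- list(cases)
  df <- validation_replicates(cases)
  ggplot2::ggplot(df, ggplot2::aes(.data$diff)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~case, scales = "free") +
    ggplot2::labs(x = "Estimated EER - true EER", y = "Replicates") +
    ggplot2::theme_minimal()
}
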