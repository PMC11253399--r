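#' @export
autoplot.exposure_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$signature, -.data$weight), y = .data$weight
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "exposure",
                  title = "Signature exposures") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.clone_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sample_id, y = .data$prevalence,
    group = .data$clone, colour = .data$clone
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$clone_fraction)) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "cancer cell fraction",
                  title = "Clonal prevalences") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.survfit_summary <- function(object, ...) {
  df <- object$curves
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$survival, colour = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "months", y = "disease-specific survival",
      subtitle = sprintf("log-rank p = %.3g", object$logrank_p)
    ) +
    ggplot2::theme_minimal()
}

#' Stacked shared/private proportion bars per tumour
#'
#' @param proportions tibble from [run_spatial()]'s `proportions`.
#' @return a ggplot.
#' @export
plot_population_proportions <- function(proportions) {
  df <- proportions |>
    dplyr::select("tumour_id", shared = "prop_shared",
                  private = "prop_private") |>
    tidyr::pivot_longer(-"tumour_id", names_to = "population",
                        values_to = "proportion")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$tumour_id, y = .data$proportion, fill = .data$population
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(shared = "grey50",
                                          private = "seagreen")) +
    ggplot2::labs(x = NULL, y = "proportion of mutations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Platinum enrichment odds ratios by population
#'
#' @param platinum tibble from [run_temporal()]'s `platinum`.
#' @return a ggplot.
#' @export
plot_platinum_scores <- function(platinum) {
  ggplot2::ggplot(platinum, ggplot2::aes(
    x = .data$population, y = .data$odds_ratio
  )) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar",
                          width = 0.4, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "platinum enrichment odds ratio") +
    ggplot2::theme_minimal()
}
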