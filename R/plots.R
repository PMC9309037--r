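#' Plot rejection rates across numbers of mountains
#'
#' Draws the empirical type I error rate (or power) of every model against
#' the number of mountains, panelled by random-effect variance and
#' aggregation policy, in the layout of the scenario figures.
#'
#' @param object A `level_grid` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.level_grid <- function(object, ...) {
  df <- object$metrics
  lab <- if (object$config$effect == "null") "Type I error rate" else "Power"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$m,
                                        y = .data$rejection_rate,
                                        colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(
      ggplot2::vars(.data$variance), ggplot2::vars(.data$singular_policy),
      labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Number of mountains", y = lab, colour = "Model") +
    ggplot2::theme_minimal()
  if (object$config$effect == "null") {
    p <- p + ggplot2::geom_hline(yintercept = object$config$alpha,
                                 linetype = "dotted")
  }
  p
}

#' Plot variance-component estimate distributions
#'
#' Violin-style distributions of per-replicate variance-component estimates
#' by number of mountains, with the generating value as a dotted line and
#' the mean estimate as a point, separately for all fits and the
#' non-singular subset.
#'
#' @param varcomp The `varcomp` tibble of a [run_grid()] result.
#' @param true_value Generating variance (dotted reference line).
#' @return A ggplot object.
#' @export
plot_varcomp <- function(varcomp, true_value = NULL) {
  long <- varcomp |>
    tidyr::pivot_longer(dplyr::all_of(c("sigma2_intercept", "sigma2_slope")),
                        names_to = "term", values_to = "estimate") |>
    dplyr::mutate(subset = "all") |>
    dplyr::bind_rows(
      varcomp |>
        dplyr::filter(!.data$singular) |>
        tidyr::pivot_longer(
          dplyr::all_of(c("sigma2_intercept", "sigma2_slope")),
          names_to = "term", values_to = "estimate") |>
        dplyr::mutate(subset = "nonsingular"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$m),
                                          y = .data$estimate)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red") +
    ggplot2::facet_grid(ggplot2::vars(.data$term),
                        ggplot2::vars(.data$subset)) +
    ggplot2::labs(x = "Number of mountains",
                  y = "Variance estimate (cm²)") +
    ggplot2::theme_minimal()
  if (!is.null(true_value)) {
    p <- p + ggplot2::geom_hline(yintercept = true_value,
                                 linetype = "dotted", colour = "blue")
  }
  p
}

#' Plot partial-effect curves of a quantile spline fit
#'
#' @param object A `quantile_spline` from [fit_quantile_spline()].
#' @param ... Unused.
#' @return A ggplot object with one panel per design covariate.
#' @export
autoplot.quantile_spline <- function(object, ...) {
  pe <- partial_effects(object)
  ggplot2::ggplot(pe, ggplot2::aes(x = .data$x, y = .data$effect)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$covariate), scales = "free_x") +
    ggplot2::labs(x = NULL, y = paste0("Median ", object$response)) +
    ggplot2::theme_minimal()
}
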