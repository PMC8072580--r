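#' Predicted-versus-actual scatter for a fitted QSAR model
#'
#' Training-set predictions against observed responses, with the identity
#' line. For an OLS fit the squared Pearson correlation of this scatter
#' equals the model's R2.
#'
#' @param model A fitted [fit_mlr()] model.
#' @return A ggplot object.
#' @export
plot_predicted_vs_actual <- function(model) {
  df <- tibble(actual = model$data[[model$spec$response]],
               predicted = unname(model$fitted))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = model$spec$label,
      subtitle = sprintf("R2 = %.4f", model$r_squared),
      x = paste("actual", model$spec$response),
      y = paste("predicted", model$spec$response)) +
    ggplot2::theme_minimal()
}

#' Standardized-coefficient bar chart
#'
#' Horizontal bars of the standardized betas (see
#' [standardized_coefficients()]), showing the direction and relative
#' strength of each descriptor's influence on the response.
#'
#' @param model A fitted [fit_mlr()] model.
#' @return A ggplot object.
#' @export
plot_standardized_coefficients <- function(model) {
  b <- standardized_coefficients(model)
  df <- tibble(term = factor(names(b), levels = rev(names(b))),
               std_beta = unname(b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$std_beta, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(title = model$spec$label, x = "standardized coefficient",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Williams plot
#'
#' Standardized residuals against leverages, with the vertical warning
#' leverage h* and the horizontal standardized-residual band. Points
#' outside either limit fall outside the model's applicability domain.
#'
#' @param ad An [williams_data()] report (or a fitted model, from which the
#'   report is computed).
#' @return A ggplot object.
#' @export
plot_williams <- function(ad) {
  if (inherits(ad, "qsar_mlr")) ad <- williams_data(ad)
  h_star <- attr(ad, "h_star")
  cutoff <- attr(ad, "residual_cutoff")
  ggplot2::ggplot(as_tibble(ad),
                  ggplot2::aes(x = .data$leverage, y = .data$std_residual)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = h_star, linetype = 2, colour = "red") +
    ggplot2::geom_hline(yintercept = c(-cutoff, cutoff), linetype = 2,
                        colour = "red") +
    ggplot2::labs(title = attr(ad, "label"),
                  subtitle = sprintf("h* = %.3f", h_star),
                  x = "leverage", y = "standardized residual") +
    ggplot2::theme_minimal()
}
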