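#' Warning leverage for the applicability domain
#'
#' The conventional cut-off of the Williams plot,
#' \eqn{h^\ast = 3(k+1)/n}, where k is the number of descriptors in the
#' model and n the number of training compounds. Observations with leverage
#' above \eqn{h^\ast} lie outside the descriptor space in which the model
#' was developed.
#'
#' @param k Number of descriptors (>= 1).
#' @param n Number of observations (> k + 1).
#' @return The warning leverage, a number in (0, 3].
#' @examples
#' warning_leverage(4, 19)  # 15/19
#' warning_leverage(3, 19)  # 12/19
#' @export
warning_leverage <- function(k, n) {
  if (k < 1) {
    abort("k must be >= 1", class = "mlcqsar_validation_error")
  }
  if (n <= k + 1) {
    abort(sprintf("invalid design: n = %d must exceed k + 1 = %d", n, k + 1),
          class = "mlcqsar_validation_error")
  }
  3 * (k + 1) / n
}

#' Williams-plot data: leverages and standardized residuals
#'
#' Computes per-compound leverages \eqn{h_{ii}} (diagonal of the hat matrix
#' of the model's design, intercept included) and internally studentized
#' residuals \eqn{e_i/(sd\sqrt{1-h_{ii}})}, flags leverage outliers against
#' the warning leverage \eqn{h^\ast = 3(k+1)/n} and response outliers
#' against a standardized-residual band (by convention +-3).
#'
#' The leverages satisfy \eqn{\sum_i h_{ii} = k + 1} and
#' \eqn{h_{ii} \in [1/n, 1]}.
#'
#' @param model A fitted [fit_mlr()] model.
#' @param residual_cutoff Half-width of the standardized-residual band
#'   (default 3).
#' @return An object of class `ad_report`: a tibble with columns
#'   `compound_id`, `leverage`, `std_residual`, `leverage_outlier`,
#'   `residual_outlier`, and attributes `h_star`, `residual_cutoff` and
#'   `label`.
#' @export
williams_data <- function(model, residual_cutoff = 3) {
  stopifnot(inherits(model, "qsar_mlr"))
  y_scale <- stats::sd(model$data[[model$spec$response]])
  if (model$sd_resid <= .Machine$double.eps^0.5 * max(y_scale, 1e-12)) {
    abort("residual standard deviation is zero; standardized residuals undefined",
          class = "mlcqsar_degenerate_standardization")
  }
  h <- unname(hatvalues(model$lm))
  k <- length(model$spec$predictors)
  h_star <- warning_leverage(k, model$n)
  std <- model$residuals / (model$sd_resid * sqrt(1 - h))
  out <- tibble(
    compound_id = names(model$residuals),
    leverage = h,
    std_residual = unname(std),
    leverage_outlier = h > h_star,
    residual_outlier = abs(unname(std)) > residual_cutoff
  )
  structure(out, h_star = h_star, residual_cutoff = residual_cutoff,
            label = model$spec$label,
            class = c("ad_report", class(out)))
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("<ad_report %s: h* = %.3f, |std residual| cutoff = %g>\n",
              attr(x, "label"), attr(x, "h_star"), attr(x, "residual_cutoff")))
  NextMethod()
}
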