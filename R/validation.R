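#' Leave-one-out cross-validation of a QSAR model
#'
#' Computes the deleted (leave-one-out) residuals without refitting, via the
#' hat-matrix identity \eqn{e_{(i)} = e_i/(1-h_{ii})}, and from them the
#' predicted residual sum of squares \eqn{PRESS = \sum e_{(i)}^2} and the
#' cross-validated coefficient of determination
#' \eqn{Q^2 = 1 - PRESS/SS_{tot}}, with \eqn{SS_{tot}} taken about the
#' training-set response mean. Two mean-square summaries are reported:
#' `mse_resid` (the residual mean square, `sd_resid^2`) and `mse_cv`
#' (`PRESS/n`). Variance inflation factors are included when the model has
#' at least two predictors.
#'
#' `press` is never smaller than the calibration SSE, so `q_squared` is
#' strictly below `r_squared` whenever the fit is imperfect.
#'
#' @param model A fitted [fit_mlr()] model.
#' @return An object of class `validation_report`: list with `label`,
#'   `press`, `q_squared`, `r_squared`, `adj_r_squared`, `mse_resid`,
#'   `mse_cv`, `loo_residuals` (named by compound) and `vif` (named, or
#'   `NULL` for a single-predictor model).
#' @export
loo_validate <- function(model) {
  stopifnot(inherits(model, "qsar_mlr"))
  p <- length(model$spec$predictors)
  if (model$n <= p + 2) {
    abort("leave-one-out validation needs n > p + 2",
          class = "mlcqsar_insufficient_data")
  }
  h <- unname(hatvalues(model$lm))
  ids <- names(model$residuals)
  if (any(h > 1 - 1e-10)) {
    abort(sprintf("degenerate leverage (h = 1) for compound %s",
                  paste(ids[h > 1 - 1e-10], collapse = ", ")),
          class = "mlcqsar_degenerate_leverage")
  }
  loo <- model$residuals / (1 - h)
  press <- sum(loo^2)
  y <- model$data[[model$spec$response]]
  ss_total <- sum((y - mean(y))^2)
  vif <- if (p >= 2) compute_vif(frame = model$data[model$spec$predictors])
         else NULL
  structure(
    list(
      label = model$spec$label,
      press = press,
      q_squared = 1 - press / ss_total,
      r_squared = model$r_squared,
      adj_r_squared = model$adj_r_squared,
      mse_resid = model$sd_resid^2,
      mse_cv = press / model$n,
      loo_residuals = setNames(unname(loo), ids),
      vif = vif
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report %s: PRESS = %.4g, Q2 = %.4f (R2 = %.4f, adj = %.4f)>\n",
    x$label, x$press, x$q_squared, x$r_squared, x$adj_r_squared))
  if (!is.null(x$vif)) {
    cat("  VIF:", paste(sprintf("%s %.2f", names(x$vif), x$vif),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Variance inflation factors
#'
#' For each predictor j, \eqn{VIF_j = 1/(1-R_j^2)} where \eqn{R_j^2} is the
#' coefficient of determination of the auxiliary regression (with
#' intercept) of predictor j on the remaining predictors. Values near 1
#' indicate orthogonal descriptors; the usual screening bound in QSAR work
#' is VIF < 5.
#'
#' @param table A [compound_table()] (used with `spec`).
#' @param spec A [model_spec()] naming at least two predictors.
#' @param frame Alternatively, a data frame of predictor columns; when
#'   given, `table`/`spec` are ignored.
#' @return Named numeric vector of VIFs, one per predictor.
#' @export
compute_vif <- function(table = NULL, spec = NULL, frame = NULL) {
  if (is.null(frame)) {
    stopifnot(inherits(spec, "model_spec"))
    frame <- model_frame(table, spec)[spec$predictors]
  }
  frame <- as.data.frame(frame)
  if (ncol(frame) < 2) {
    abort("VIF needs at least two predictors",
          class = "mlcqsar_insufficient_data")
  }
  vifs <- vapply(seq_along(frame), function(j) {
    r2 <- suppressWarnings(
      summary(lm(frame[[j]] ~ ., data = frame[-j]))$r.squared)
    if (r2 > 1 - 1e-12) {
      abort(sprintf(
        "perfect collinearity: predictor '%s' is an exact linear combination of the others",
        names(frame)[j]),
            class = "mlcqsar_collinearity_error")
    }
    1 / (1 - r2)
  }, numeric(1))
  setNames(vifs, names(frame))
}
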