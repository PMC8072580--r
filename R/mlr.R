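#' Specify a QSAR regression model
#'
#' A model specification names the pharmacokinetic response, the ordered set
#' of descriptors entering the linear model, and an optional label used in
#' reports.
#'
#' @param response One of `"log_Kp"`, `"log_KaHSA"`, `"log_BB"`,
#'   `"caco2_e06"`, `"fu_brain"`.
#' @param predictors Character vector of descriptor names, a subset of
#'   `log_km`, `log_k01`, `log_kw_iam`, `log_kw_ods`, `tpsa`, `alpha`, `mw`.
#' @param label Short tag for reports (defaults to `response ~ predictors`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, predictors, label = NULL) {
  if (!is.character(response) || length(response) != 1) {
    abort("response must be a single name", class = "mlcqsar_spec_error")
  }
  if (!length(predictors)) {
    abort("predictors must be non-empty", class = "mlcqsar_spec_error")
  }
  if (anyDuplicated(predictors)) {
    abort("duplicated predictor names", class = "mlcqsar_spec_error")
  }
  if (response %in% predictors) {
    abort("response must not appear among the predictors",
          class = "mlcqsar_spec_error")
  }
  structure(
    list(response = response, predictors = as.character(predictors),
         label = label %||% paste0(response, " ~ ",
                                   paste(predictors, collapse = " + "))),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s: %s ~ %s>\n", x$label, x$response,
              paste(x$predictors, collapse = " + ")))
  invisible(x)
}

#' The twenty model specifications of the reference study
#'
#' One specification per published equation: each of the five
#' pharmacokinetic responses regressed on one chromatographic lipophilicity
#' descriptor (`log_km`, `log_kw_iam`, `log_kw_ods` or `log_k01`) plus the
#' structural/electronic descriptors used with that response (TPSA is
#' omitted for HSA binding, polarizability for Caco-2 and the unbound brain
#' fraction, MW for the blood-brain ratio).
#'
#' @return A named list of [model_spec()] objects, labels `"Eq3"`..`"Eq22"`.
#' @export
paper_model_specs <- function() {
  ref <- reference_fit_stats()
  specs <- lapply(seq_len(nrow(ref)), function(i) {
    model_spec(ref$response[i],
               strsplit(ref$predictors[i], ";", fixed = TRUE)[[1]],
               label = ref$label[i])
  })
  names(specs) <- ref$label
  specs
}

# Assemble the modelling frame for a spec: one row per compound with
# complete response + predictor values. Descriptor columns may live either
# in the compounds slot (mw, tpsa, alpha) or in the derived descriptors.
model_frame <- function(table, spec) {
  validate_compound_table(table)
  cols <- c(spec$response, spec$predictors)
  frame <- tibble(compound_id = table$compounds$compound_id)
  for (col in cols) {
    if (col %in% names(table$compounds)) {
      frame[[col]] <- table$compounds[[col]]
    } else if (col %in% names(table$descriptors)) {
      frame[[col]] <- table$descriptors[[col]][
        match(frame$compound_id, table$descriptors$compound_id)]
    } else {
      abort(sprintf("column '%s' not found in compound table", col),
            class = "mlcqsar_schema_error")
    }
  }
  frame[complete.cases(frame[cols]), ]
}

#' Fit a QSAR multiple linear regression
#'
#' Ordinary least squares with intercept of one pharmacokinetic response on
#' the descriptors named in the specification, over the compounds with
#' complete data (missing cells are excluded listwise). The solver is the
#' QR decomposition used by [stats::lm()]. Reported global statistics follow
#' the usual definitions: residual standard deviation
#' \eqn{sd = \sqrt{SSE/(n-p-1)}}, overall
#' \eqn{F = (R^2/p) / ((1-R^2)/(n-p-1))} with p-value from the F(p, n-p-1)
#' distribution, and \eqn{adj\,R^2 = 1-(1-R^2)(n-1)/(n-p-1)}.
#'
#' @param table A [compound_table()] providing response and descriptor
#'   columns.
#' @param spec A [model_spec()].
#' @return An object of class `qsar_mlr`: list with `spec`, `n`,
#'   `coefficients` (tibble: term, estimate, std_error), `r_squared`,
#'   `adj_r_squared`, `sd_resid`, `f_stat`, `p_value`, `fitted` and
#'   `residuals` (named by compound), `data` (the modelling frame) and the
#'   underlying `lm` fit.
#' @examples
#' tab <- bundled_paper_dataset()
#' fit_mlr(tab, model_spec("log_BB", c("log_km", "tpsa", "alpha"), "Eq9"))
#' @export
fit_mlr <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  frame <- model_frame(table, spec)
  p <- length(spec$predictors)
  n <- nrow(frame)
  if (n <= p + 1) {
    abort(sprintf(
      "insufficient data: n = %d observations for %d predictors (need n > p + 1)",
      n, p), class = "mlcqsar_insufficient_data")
  }
  fml <- stats::reformulate(spec$predictors, response = spec$response)
  fit <- lm(fml, data = frame)
  if (fit$rank < p + 1) {
    aliased <- names(which(is.na(coef(fit))))
    abort(sprintf("rank-deficient design; collinear column(s): %s",
                  paste(aliased, collapse = ", ")),
          class = "mlcqsar_collinearity_error")
  }
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  sd_resid <- sm$sigma
  f_stat <- (r2 / p) / ((1 - r2) / (n - p - 1))
  structure(
    list(
      spec = spec,
      n = n,
      coefficients = tibble(
        term = rownames(sm$coefficients),
        estimate = unname(sm$coefficients[, 1]),
        std_error = unname(sm$coefficients[, 2])
      ),
      r_squared = r2,
      adj_r_squared = sm$adj.r.squared,
      sd_resid = sd_resid,
      f_stat = f_stat,
      p_value = stats::pf(f_stat, p, n - p - 1, lower.tail = FALSE),
      fitted = setNames(unname(fit$fitted.values), frame$compound_id),
      residuals = setNames(unname(fit$residuals), frame$compound_id),
      data = frame,
      lm = fit
    ),
    class = "qsar_mlr"
  )
}

#' Render a fitted model as an `estimate(se)` equation string
#'
#' @param model A fitted [fit_mlr()] model.
#' @param digits Decimals for each coefficient and standard error.
#' @return A single string, e.g.
#'   `"log_BB = -0.046(0.155) + 0.016(0.021)*log_km - ..."`.
#' @export
equation_string <- function(model, digits = 3) {
  co <- model$coefficients
  fmt <- function(est, se) sprintf("%.*f(%.*f)", digits, est, digits, se)
  terms <- fmt(co$estimate[1], co$std_error[1])
  for (i in seq_len(nrow(co))[-1]) {
    sign <- if (co$estimate[i] < 0) " - " else " + "
    terms <- paste0(terms, sign,
                    fmt(abs(co$estimate[i]), co$std_error[i]),
                    "*", co$term[i])
  }
  paste0(model$spec$response, " = ", terms)
}

#' @export
print.qsar_mlr <- function(x, ...) {
  cat(sprintf("<qsar_mlr %s>\n  %s\n", x$spec$label, equation_string(x)))
  cat(sprintf(
    "  n = %d, R2 = %.4f, adj R2 = %.4f, sd = %.3f, F = %.1f, p = %.6f\n",
    x$n, x$r_squared, x$adj_r_squared, x$sd_resid, x$f_stat, x$p_value))
  invisible(x)
}

#' Predict responses for a compound table
#'
#' Applies the fitted linear combination to the descriptor values of
#' `table`. For the training table, predictions equal the model's fitted
#' values.
#'
#' @param object A fitted [fit_mlr()] model.
#' @param table A [compound_table()]; defaults to the training frame.
#' @param ... Unused.
#' @return Named numeric vector of predictions (names = compound ids).
#' @export
predict.qsar_mlr <- function(object, table = NULL, ...) {
  if (is.null(table)) return(object$fitted)
  validate_compound_table(table)
  frame <- tibble(compound_id = table$compounds$compound_id)
  for (col in object$spec$predictors) {
    if (col %in% names(table$compounds)) {
      frame[[col]] <- table$compounds[[col]]
    } else if (col %in% names(table$descriptors)) {
      frame[[col]] <- table$descriptors[[col]][
        match(frame$compound_id, table$descriptors$compound_id)]
    } else {
      abort(sprintf("missing predictor '%s' in compound table", col),
            class = "mlcqsar_schema_error")
    }
  }
  co <- object$coefficients
  pred <- rep(co$estimate[1], nrow(frame))
  for (i in seq_len(nrow(co))[-1]) {
    pred <- pred + co$estimate[i] * frame[[co$term[i]]]
  }
  setNames(pred, frame$compound_id)
}

#' Standardized regression coefficients
#'
#' Scale-free effect sizes \eqn{\beta_j^\ast = b_j\,s(x_j)/s(y)} computed
#' with the sample standard deviations of the training data; the intercept
#' is excluded. These are the quantities usually plotted to compare the
#' direction and strength of each descriptor's influence on the response.
#'
#' @param model A fitted [fit_mlr()] model.
#' @return Named numeric vector of standardized betas, one per predictor.
#' @export
standardized_coefficients <- function(model) {
  frame <- model$data
  y_sd <- sd(frame[[model$spec$response]])
  co <- model$coefficients[-1, ]
  x_sd <- vapply(co$term, function(t) sd(frame[[t]]), numeric(1))
  if (any(x_sd == 0)) {
    abort(sprintf("zero-variance predictor: %s",
                  paste(co$term[x_sd == 0], collapse = ", ")),
          class = "mlcqsar_validation_error")
  }
  setNames(co$estimate * x_sd / y_sd, co$term)
}
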