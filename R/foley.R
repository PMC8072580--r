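#' Fit the Foley solute-micelle binding model to a micellar retention series
#'
#' In micellar liquid chromatography the retention factor k decreases with
#' the micellized surfactant concentration \eqn{[M]} according to
#' \deqn{1/k = 1/k_m + (K_{AM}/k_m)\,[M],}
#' where \eqn{k_m} is the retention factor at zero micelle concentration and
#' \eqn{K_{AM}} (L/mol) the solute-micelle binding constant. The model is
#' fitted by unweighted ordinary least squares on the transformed scale
#' (1/k against \eqn{[M]}); \eqn{k_m} and \eqn{K_{AM}} follow from the
#' intercept and slope, and `log_km = log10(k_m)` is the micellar
#' lipophilicity descriptor.
#'
#' `cmc` is subtracted from the nominal surfactant molarity to form
#' \eqn{[M]}. It defaults to 0: for Brij 35 the critical micelle
#' concentration (~9e-5 mol/L) is negligible against working concentrations
#' of 0.075-0.150 mol/L.
#'
#' For a solute retained strongly at every concentration the intercept 1/k_m
#' can be statistically indistinguishable from zero; when the estimate is
#' not positive, `k_m` is undefined and a `mlcqsar_degenerate_fit` error is
#' raised. A constant series (zero slope) is degenerate in the opposite,
#' harmless sense: `k_am = 0`, `km` equals the common retention factor, and
#' `r_squared` is reported as 1 (the line reproduces the data exactly).
#'
#' @param series A retention series: data frame with columns `x` (surfactant
#'   molarity, mol/L) and `k` (retention factor), such as returned by
#'   [retention_series()]. If a `x_kind` column is present it must be
#'   `"surfactant_molarity"`.
#' @param cmc Critical micelle concentration (mol/L) subtracted from `x`.
#' @param on_degenerate What to do when the transformed intercept is not
#'   positive: `"error"` (default) raises `mlcqsar_degenerate_fit`; `"na"`
#'   returns the fit with `km`, `k_am` and `log_km` set to `NA` while
#'   keeping the well-defined transformed-scale quantities (`intercept`,
#'   `slope`, `r_squared`).
#' @return An object of class `foley_fit`: a list with elements `km`,
#'   `k_am`, `log_km`, `intercept` (1/k_m), `slope` (K_AM/k_m, L/mol),
#'   `r_squared` (of the transformed linear fit), `n_points` and
#'   `compound_id`.
#' @examples
#' s <- tibble::tibble(x = c(0.075, 0.1, 0.125, 0.15),
#'                     k = 50 / (1 + 20 * c(0.075, 0.1, 0.125, 0.15)))
#' fit_foley(s)
#' @export
fit_foley <- function(series, cmc = 0, on_degenerate = c("error", "na")) {
  on_degenerate <- match.arg(on_degenerate)
  series <- as_tibble(series)
  if ("x_kind" %in% names(series) &&
      any(series$x_kind != "surfactant_molarity")) {
    abort("fit_foley() requires a surfactant_molarity series",
          class = "mlcqsar_validation_error")
  }
  x <- series$x
  k <- series$k
  keep <- !is.na(x) & !is.na(k)
  x <- x[keep]; k <- k[keep]
  if (length(unique(x)) < 3) {
    abort("Foley fit needs at least 3 distinct surfactant concentrations",
          class = "mlcqsar_insufficient_data")
  }
  if (any(k <= 0)) {
    abort("retention factors must be > 0", class = "mlcqsar_validation_error")
  }
  m <- x - cmc
  if (any(m <= 0)) {
    abort("all concentrations must exceed the CMC",
          class = "mlcqsar_validation_error")
  }
  fit <- lm(y ~ m, data = data.frame(y = 1 / k, m = m))
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)[2])
  degenerate <- a <= 0
  if (degenerate && on_degenerate == "error") {
    abort(sprintf(
      "degenerate Foley fit: non-positive intercept %.4g, k_m undefined", a),
      class = "mlcqsar_degenerate_fit")
  }
  sst <- sum((1 / k - mean(1 / k))^2)
  r2 <- if (sst < .Machine$double.eps) 1 else
    suppressWarnings(summary(fit)$r.squared)
  structure(
    list(
      compound_id = if ("compound_id" %in% names(series))
        series$compound_id[1] else NA_character_,
      km = if (degenerate) NA_real_ else 1 / a,
      k_am = if (degenerate) NA_real_ else b / a,
      log_km = if (degenerate) NA_real_ else log10(1 / a),
      intercept = a,
      slope = b,
      r_squared = r2,
      n_points = length(k),
      cmc = cmc
    ),
    class = "foley_fit"
  )
}

#' @export
print.foley_fit <- function(x, ...) {
  cat(sprintf(
    "<foley_fit%s: log k_m = %.3f (k_m = %.2f), K_AM = %.2f L/mol, R2 = %.4f, n = %d>\n",
    if (is.na(x$compound_id)) "" else paste0(" ", x$compound_id),
    x$log_km, x$km, x$k_am, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit the Foley model to every micellar series of a compound table
#'
#' Runs [fit_foley()] per compound on the MLC retention series. Compounds
#' whose fit fails (missing series, fewer than 3 points, or a degenerate
#' non-positive intercept) are collected in the failure table rather than
#' aborting the batch. Fitted `log_km` values are written into the returned
#' table's derived descriptors as `log_km_fitted`, leaving any descriptor
#' column loaded from data untouched.
#'
#' @param table A [compound_table()] whose retention slot contains MLC
#'   series.
#' @param cmc Critical micelle concentration (mol/L), see [fit_foley()].
#' @return A list with elements
#'   \describe{
#'     \item{fits}{named list of `foley_fit` objects,}
#'     \item{summary}{tibble with one row per fitted compound
#'       (`compound_id`, `km`, `k_am`, `log_km`, `r_squared`, `n_points`),}
#'     \item{failures}{tibble (`compound_id`, `message`) of compounds that
#'       could not be fitted,}
#'     \item{table}{the input table with `log_km_fitted` added to its
#'       descriptors.}
#'   }
#' @export
fit_foley_batch <- function(table, cmc = 0) {
  validate_compound_table(table)
  ids <- table$compounds$compound_id
  fits <- list()
  fail_id <- character()
  fail_msg <- character()
  for (id in ids) {
    s <- retention_series(table, id, "MLC")
    res <- tryCatch({
      if (!nrow(s)) {
        abort("no MLC retention series", class = "mlcqsar_insufficient_data")
      }
      fit_foley(s, cmc = cmc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail_id <- c(fail_id, id)
      fail_msg <- c(fail_msg, conditionMessage(res))
    } else {
      fits[[id]] <- res
    }
  }
  summary <- tibble(
    compound_id = names(fits),
    km = vapply(fits, `[[`, numeric(1), "km"),
    k_am = vapply(fits, `[[`, numeric(1), "k_am"),
    log_km = vapply(fits, `[[`, numeric(1), "log_km"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    n_points = vapply(fits, `[[`, integer(1), "n_points")
  )
  out <- table
  out$descriptors$log_km_fitted <-
    summary$log_km[match(out$descriptors$compound_id, summary$compound_id)]
  list(
    fits = fits,
    summary = summary,
    failures = tibble(compound_id = fail_id, message = fail_msg),
    table = out
  )
}
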