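#' Extrapolate isocratic retention to a purely aqueous eluent (log k_w)
#'
#' In reversed-phase liquid chromatography with a binary aqueous-organic
#' eluent, log10 of the retention factor is, to good approximation, linear
#' in the organic-modifier volume fraction \eqn{\varphi}:
#' \deqn{\log k = \log k_w - S\,\varphi.}
#' The intercept \eqn{\log k_w} -- retention extrapolated to pure water --
#' is the standard chromatographic lipophilicity descriptor; \eqn{S} is the
#' (positive, for retention decreasing with modifier) eluent-strength slope.
#' The fit is ordinary least squares of `log10(k)` on `x`.
#'
#' Because \eqn{\varphi = 0} usually lies outside the measured range (e.g.
#' acetonitrile fractions 0.2-0.5), `log_kw` is an extrapolation; its
#' reported standard error `se_log_kw` grows with the distance of 0 from the
#' sampled \eqn{\varphi} values.
#'
#' @param series A retention series: data frame with columns `x`
#'   (modifier volume fraction) and `k` (retention factor, > 0). If an
#'   `x_kind` column is present it must be `"modifier_volume_fraction"`.
#' @return An object of class `extrapolation_fit`: list with `log_kw`,
#'   `se_log_kw`, `s_slope` (the magnitude \eqn{S}), `r_squared`,
#'   `n_points` and `compound_id`.
#' @examples
#' phi <- c(0.2, 0.3, 0.4, 0.5)
#' s <- tibble::tibble(x = phi, k = 10^(2 - 4 * phi))
#' fit_log_kw(s)
#' @export
fit_log_kw <- function(series) {
  series <- as_tibble(series)
  if ("x_kind" %in% names(series) &&
      any(series$x_kind != "modifier_volume_fraction")) {
    abort("fit_log_kw() requires a modifier_volume_fraction series",
          class = "mlcqsar_validation_error")
  }
  x <- series$x
  k <- series$k
  keep <- !is.na(x) & !is.na(k)
  x <- x[keep]; k <- k[keep]
  if (length(unique(x)) < 3) {
    abort("log k_w extrapolation needs at least 3 distinct modifier fractions",
          class = "mlcqsar_insufficient_data")
  }
  if (any(k <= 0)) {
    abort("retention factors must be > 0", class = "mlcqsar_validation_error")
  }
  fit <- lm(y ~ x, data = data.frame(y = log10(k), x = x))
  sm <- suppressWarnings(summary(fit))
  y <- log10(k)
  sst <- sum((y - mean(y))^2)
  structure(
    list(
      compound_id = if ("compound_id" %in% names(series))
        series$compound_id[1] else NA_character_,
      log_kw = unname(coef(fit)[1]),
      se_log_kw = unname(sm$coefficients[1, 2]),
      s_slope = -unname(coef(fit)[2]),
      r_squared = if (sst < .Machine$double.eps) 1 else sm$r.squared,
      n_points = length(k)
    ),
    class = "extrapolation_fit"
  )
}

#' @export
print.extrapolation_fit <- function(x, ...) {
  cat(sprintf(
    "<extrapolation_fit%s: log k_w = %.3f (se %.3f), S = %.3f, R2 = %.4f, n = %d>\n",
    if (is.na(x$compound_id)) "" else paste0(" ", x$compound_id),
    x$log_kw, x$se_log_kw, x$s_slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Batch log k_w extrapolation over a compound table
#'
#' Applies [fit_log_kw()] to every compound that has a
#' modifier-volume-fraction series in the requested system and writes the
#' intercepts into the table's derived descriptors (`log_kw_iam` for IAM,
#' `log_kw_ods` for ODS).
#'
#' @param table A [compound_table()].
#' @param system `"IAM"` or `"ODS"`.
#' @return A list with `fits` (named list), `summary` (tibble), `failures`
#'   (tibble) and `table` (updated compound table), mirroring
#'   [fit_foley_batch()].
#' @export
fit_log_kw_batch <- function(table, system = c("IAM", "ODS")) {
  system <- match.arg(system)
  validate_compound_table(table)
  ids <- table$compounds$compound_id
  fits <- list()
  fail_id <- character(); fail_msg <- character()
  for (id in ids) {
    s <- retention_series(table, id, system)
    res <- tryCatch({
      if (!nrow(s)) {
        abort(sprintf("no %s retention series", system),
              class = "mlcqsar_insufficient_data")
      }
      fit_log_kw(s)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail_id <- c(fail_id, id); fail_msg <- c(fail_msg, conditionMessage(res))
    } else {
      fits[[id]] <- res
    }
  }
  summary <- tibble(
    compound_id = names(fits),
    system = system,
    log_kw = vapply(fits, `[[`, numeric(1), "log_kw"),
    se_log_kw = vapply(fits, `[[`, numeric(1), "se_log_kw"),
    s_slope = vapply(fits, `[[`, numeric(1), "s_slope"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    n_points = vapply(fits, `[[`, integer(1), "n_points")
  )
  out <- table
  col <- if (system == "IAM") "log_kw_iam" else "log_kw_ods"
  vals <- summary$log_kw[match(out$descriptors$compound_id,
                               summary$compound_id)]
  have <- !is.na(vals)
  if (!col %in% names(out$descriptors)) out$descriptors[[col]] <- NA_real_
  out$descriptors[[col]][have] <- vals[have]
  list(fits = fits, summary = summary,
       failures = tibble(compound_id = fail_id, message = fail_msg),
       table = out)
}
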