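#' Ground truth for a synthetic micellar retention series
#'
#' Bundles the generating parameters for [gen_foley_series()]: the forward
#' model is \eqn{k_i = k_m/(1 + K_{AM} x_i)} with optional multiplicative
#' lognormal noise. Retention factors are positive and ratio-scaled, so the
#' noise is multiplicative with a mean-one lognormal factor whose
#' coefficient of variation is `noise_cv`.
#'
#' @param km Retention factor at zero micelle concentration (> 0).
#' @param k_am Solute-micelle binding constant, L/mol (>= 0).
#' @param concentrations Surfactant molarity grid (defaults to the
#'   0.075-0.150 mol/L grid used throughout the package).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed Optional integer seed for reproducible draws.
#' @return An object of class `foley_truth`.
#' @export
foley_truth <- function(km, k_am,
                        concentrations = c(0.075, 0.100, 0.125, 0.150),
                        noise_cv = 0, seed = NULL) {
  if (km <= 0) abort("km must be > 0", class = "mlcqsar_validation_error")
  if (k_am < 0) abort("k_am must be >= 0", class = "mlcqsar_validation_error")
  if (noise_cv < 0) {
    abort("noise_cv must be >= 0", class = "mlcqsar_validation_error")
  }
  structure(list(km = km, k_am = k_am, concentrations = concentrations,
                 noise_cv = noise_cv, seed = seed),
            class = "foley_truth")
}

#' Generate a micellar retention series with known ground truth
#'
#' Evaluates the solute-micelle binding forward model
#' \eqn{k_i = k_m/(1 + K_{AM} x_i)} on the truth's concentration grid and,
#' if `noise_cv > 0`, multiplies each point by an independent mean-one
#' lognormal factor with that coefficient of variation
#' (\eqn{\sigma_{\log}^2 = \log(1 + cv^2)}). Draws are deterministic under
#' a fixed `seed`.
#'
#' @param truth A [foley_truth()].
#' @param compound_id Label attached to the series.
#' @return A retention-series tibble (`compound_id`, `system`, `x_kind`,
#'   `x`, `k`) suitable for [fit_foley()].
#' @examples
#' tr <- foley_truth(km = 50, k_am = 20)
#' gen_foley_series(tr)$k  # 20, 16.667, 14.286, 12.5
#' @export
gen_foley_series <- function(truth, compound_id = "synthetic") {
  stopifnot(inherits(truth, "foley_truth"))
  if (!is.null(truth$seed)) set.seed(truth$seed)
  x <- truth$concentrations
  k <- truth$km / (1 + truth$k_am * x)
  if (truth$noise_cv > 0) {
    sdlog <- sqrt(log1p(truth$noise_cv^2))
    k <- k * exp(rnorm(length(k), -sdlog^2 / 2, sdlog))
  }
  tibble(compound_id = compound_id, system = "MLC",
         x_kind = "surfactant_molarity", x = x, k = k)
}

#' Ground truth for a synthetic descriptor/response table
#'
#' Bundles the generating parameters for [gen_qsar_table()]: true
#' regression coefficients, per-descriptor uniform sampling ranges, and
#' additive Gaussian response noise (the assumption under which the OLS
#' models are fitted). The defaults emulate the bundled study's conditions:
#' 19 compounds, descriptor spans matching the data (`log_km` 0.3-2.9,
#' TPSA 48-75 A^2, polarizability 25-34 A^3, MW 256-356 g/mol), a skin
#' permeation response generated with coefficients 0.272, -0.025, 0.041 and
#' 0.003 about an intercept of -7.137, and a residual noise of 0.108 log
#' units.
#'
#' @param n_compounds Number of synthetic compounds (> number of
#'   descriptors + 2).
#' @param coefficients Named numeric vector: `intercept` plus one true beta
#'   per descriptor.
#' @param descriptor_ranges Named list of `c(lower, upper)` sampling bounds,
#'   one per descriptor named in `coefficients`.
#' @param noise_sd Gaussian response noise, response units (>= 0).
#' @param response Name of the generated response column.
#' @param descriptor_correlation Optional common correlation in (0, 1)
#'   imposed across descriptors through a Gaussian copula, to exercise
#'   collinearity diagnostics; 0 (default) samples independently.
#' @param seed Optional integer seed.
#' @return An object of class `qsar_truth`.
#' @export
qsar_truth <- function(n_compounds = 19,
                       coefficients = c(intercept = -7.137, log_km = 0.272,
                                        tpsa = -0.025, alpha = 0.041,
                                        mw = 0.003),
                       descriptor_ranges = list(log_km = c(0.3, 2.9),
                                                tpsa = c(48, 75),
                                                alpha = c(25, 34),
                                                mw = c(256, 356)),
                       noise_sd = 0.108, response = "log_Kp",
                       descriptor_correlation = 0, seed = NULL) {
  if (!"intercept" %in% names(coefficients)) {
    abort("coefficients must include an 'intercept' element",
          class = "mlcqsar_validation_error")
  }
  descr <- setdiff(names(coefficients), "intercept")
  if (!setequal(descr, names(descriptor_ranges))) {
    abort("descriptor_ranges must name exactly the non-intercept coefficients",
          class = "mlcqsar_validation_error")
  }
  if (n_compounds <= length(descr) + 2) {
    abort("n_compounds must exceed the number of descriptors + 2",
          class = "mlcqsar_validation_error")
  }
  if (noise_sd < 0) {
    abort("noise_sd must be >= 0", class = "mlcqsar_validation_error")
  }
  if (descriptor_correlation < 0 || descriptor_correlation >= 1) {
    abort("descriptor_correlation must lie in [0, 1)",
          class = "mlcqsar_validation_error")
  }
  structure(list(n_compounds = n_compounds, coefficients = coefficients,
                 descriptor_ranges = descriptor_ranges, noise_sd = noise_sd,
                 response = response,
                 descriptor_correlation = descriptor_correlation,
                 seed = seed),
            class = "qsar_truth")
}

#' Generate a synthetic descriptor/response table with known ground truth
#'
#' Samples each descriptor uniformly within its range (independently, or
#' through an equicorrelated Gaussian copula when
#' `descriptor_correlation > 0`), evaluates the linear model
#' `response = intercept + sum(beta_j * x_j)` and adds Gaussian noise of sd
#' `noise_sd`. Deterministic under a fixed seed. Structural descriptors
#' (`mw`, `tpsa`, `alpha`) are placed in the compounds slot,
#' chromatographic ones in the derived-descriptor slot, mirroring how
#' measured data are laid out.
#'
#' @param truth A [qsar_truth()].
#' @return A [compound_table()] with the generating `truth` attached as
#'   attribute `"truth"`.
#' @export
gen_qsar_table <- function(truth) {
  stopifnot(inherits(truth, "qsar_truth"))
  if (!is.null(truth$seed)) set.seed(truth$seed)
  n <- truth$n_compounds
  descr <- setdiff(names(truth$coefficients), "intercept")
  rho <- truth$descriptor_correlation
  u <- if (rho > 0) {
    z0 <- rnorm(n)
    sapply(descr, function(d) {
      pnorm(sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(n))
    })
  } else {
    sapply(descr, function(d) runif(n))
  }
  u <- matrix(u, nrow = n, dimnames = list(NULL, descr))
  X <- sapply(descr, function(d) {
    r <- truth$descriptor_ranges[[d]]
    r[1] + (r[2] - r[1]) * u[, d]
  })
  X <- matrix(X, nrow = n, dimnames = list(NULL, descr))
  y <- truth$coefficients[["intercept"]] +
    drop(X %*% truth$coefficients[descr])
  if (truth$noise_sd > 0) y <- y + rnorm(n, 0, truth$noise_sd)

  ids <- sprintf("S%02d", seq_len(n))
  structural <- intersect(descr, c("mw", "tpsa", "alpha"))
  chromatographic <- setdiff(descr, structural)
  compounds <- tibble(compound_id = ids)
  for (d in structural) compounds[[d]] <- X[, d]
  # required structural columns default to mid-range placeholders when the
  # truth does not generate them, so the table still validates
  for (d in setdiff(c("mw", "tpsa", "alpha"), structural)) {
    compounds[[d]] <- switch(d, mw = 300, tpsa = 60, alpha = 30)
  }
  compounds[[truth$response]] <- unname(y)
  descriptors <- tibble(compound_id = ids)
  for (d in chromatographic) descriptors[[d]] <- X[, d]
  out <- compound_table(compounds, descriptors = descriptors)
  attr(out, "truth") <- truth
  out
}
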