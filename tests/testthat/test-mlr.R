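tab <- bundled_paper_dataset()

test_that("the skin-permeation model on the bundled data matches its published fit quality", {
  m <- fit_mlr(tab, paper_spec("Eq3"))
  expect_equal(m$n, 19L)
  expect_lt(abs(m$r_squared - 0.9593), 5e-4)
  expect_lt(abs(m$sd_resid - 0.108), 1.5e-3)
  expect_equal(round(m$f_stat), 82)
  expect_lt(m$p_value, 1e-6)
})

test_that("models built on directly tabulated descriptors reproduce printed statistics exactly", {
  # the aqueous-extrapolated and single-eluent descriptors enter the fit
  # exactly as tabulated, so every printed figure is recovered to its
  # last printed decimal
  for (lbl in c("Eq4", "Eq5", "Eq18")) {
    m <- fit_mlr(tab, paper_spec(lbl))
    ref <- reference_fit_stats()
    i <- which(ref$label == lbl)
    expect_true(matches_printed(m$r_squared, ref$r_squared[i]))
    expect_true(matches_printed(m$sd_resid, ref$sd[i]))
    expect_true(matches_printed(round(m$f_stat), ref$f[i]))
    rc <- reference_coefficients()
    rc <- rc[rc$label == lbl, ]
    for (j in seq_len(nrow(rc))) {
      est <- m$coefficients$estimate[m$coefficients$term == rc$term[j]]
      expect_true(matches_printed(est, rc$estimate[j]),
                  label = paste(lbl, rc$term[j]))
    }
  }
})

test_that("an exactly linear response is recovered to machine precision", {
  syn <- noiseless_table(n = 12, seed = 42)
  truth <- attr(syn, "truth")
  m <- fit_mlr(syn, model_spec("log_Kp", c("log_km", "tpsa", "alpha", "mw")))
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_lt(m$sd_resid, 1e-10)
  est <- setNames(m$coefficients$estimate, m$coefficients$term)
  expect_lt(abs(est[["(Intercept)"]] - truth$coefficients[["intercept"]]),
            1e-9)
  for (d in c("log_km", "tpsa", "alpha", "mw")) {
    expect_lt(abs(est[[d]] - truth$coefficients[[d]]), 1e-10)
  }
})

test_that("QR fit equals the explicit normal-equations oracle on random designs", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(7:15, 1)
    # keep the design well-conditioned so the explicit normal-equations
    # oracle is itself accurate to full precision
    X <- data.frame(tpsa = runif(n), alpha = 0.5 + runif(n))
    y <- 1 + 2 * X$tpsa - X$alpha + rnorm(n, 0, 0.3)
    cmp <- tibble::tibble(compound_id = as.character(seq_len(n)),
                          mw = 300, tpsa = X$tpsa, alpha = X$alpha,
                          log_BB = y)
    m <- fit_mlr(compound_table(cmp), model_spec("log_BB", c("tpsa", "alpha")))
    o <- ols_pinv(X, y)
    expect_equal(m$coefficients$estimate, unname(o$coef), tolerance = 1e-10)
    expect_equal(m$coefficients$std_error, unname(o$se), tolerance = 1e-10)
    expect_equal(m$sd_resid, o$sigma, tolerance = 1e-10)
  }
})

test_that("residuals are orthogonal to the design and sum to zero", {
  for (lbl in c("Eq3", "Eq9", "Eq15")) {
    m <- fit_mlr(tab, paper_spec(lbl))
    expect_lt(abs(sum(m$residuals)), 1e-8)
    for (p in m$spec$predictors) {
      expect_lt(abs(sum(m$residuals * m$data[[p]])), 1e-6)
    }
  }
})

test_that("adjusted R2 follows its closed form and matches the published value", {
  m <- fit_mlr(tab, paper_spec("Eq4"))
  n <- m$n; p <- length(m$spec$predictors)
  expect_equal(m$adj_r_squared,
               1 - (1 - m$r_squared) * (n - 1) / (n - p - 1),
               tolerance = 1e-12)
  expect_lt(abs(m$adj_r_squared - 0.9585), 1.5e-4)
})

test_that("predictions reproduce fitted values and degenerate rows sensibly", {
  m <- fit_mlr(tab, paper_spec("Eq3"))
  expect_equal(predict(m, tab), m$fitted, tolerance = 1e-12)
  # squared correlation of predictions with the response is the model R2
  expect_equal(cor(predict(m), tab$compounds$log_Kp)^2, m$r_squared,
               tolerance = 1e-12)
  # the blood-brain model predicts the hydrophilic series-C lead compound
  # to stay below the blood concentration (negative log BB)
  m9 <- fit_mlr(tab, paper_spec("Eq9"))
  expect_lt(predict(m9, tab)[["15"]], 0)

  z <- tab
  z$compounds[z$compounds$compound_id == "1",
              c("tpsa", "alpha", "mw")] <- list(0, 1e-12, 1e-12)
  z$descriptors$log_km[z$descriptors$compound_id == "1"] <- 0
  expect_equal(unname(predict(m, z)["1"]), m$coefficients$estimate[1],
               tolerance = 1e-8)
})

test_that("standardized coefficients are scale-invariant with the expected signs", {
  m <- fit_mlr(tab, paper_spec("Eq3"))
  b <- standardized_coefficients(m)
  expect_gt(b[["log_km"]], 0)
  expect_lt(b[["tpsa"]], 0)

  # rescaling a predictor by 1000 leaves its standardized beta unchanged
  z <- tab
  z$compounds$mw <- z$compounds$mw * 1000
  b2 <- standardized_coefficients(fit_mlr(z, paper_spec("Eq3")))
  expect_equal(unname(b2), unname(b), tolerance = 1e-10)

  # fitting on z-scored copies makes raw betas equal standardized betas;
  # the z-scored descriptors live in the derived-descriptor slot, which
  # carries no sign constraints
  zs <- tab
  for (col in c("tpsa", "alpha", "mw")) {
    zs$descriptors[[paste0("z_", col)]] <-
      as.numeric(scale(zs$compounds[[col]]))
  }
  zs$descriptors$z_log_km <- as.numeric(scale(zs$descriptors$log_km))
  zs$compounds$log_Kp <- as.numeric(scale(zs$compounds$log_Kp))
  mz <- fit_mlr(zs, model_spec("log_Kp", paste0("z_", c("log_km", "tpsa",
                                                        "alpha", "mw"))))
  expect_equal(mz$coefficients$estimate[-1],
               unname(standardized_coefficients(mz)), tolerance = 1e-10)
})

test_that("rank deficiency, small n, and missing columns raise typed errors", {
  z <- tab
  z$compounds$alpha <- 2 * z$compounds$mw    # exact collinearity
  expect_error(fit_mlr(z, paper_spec("Eq3")),
               class = "mlcqsar_collinearity_error")

  small <- tab
  small$compounds <- small$compounds[1:5, ]
  small$retention <- small$retention[small$retention$compound_id %in%
                                       small$compounds$compound_id, ]
  small$descriptors <- small$descriptors[1:5, ]
  expect_error(fit_mlr(small, paper_spec("Eq3")),
               class = "mlcqsar_insufficient_data")

  expect_error(fit_mlr(tab, model_spec("log_Kp", c("nonexistent", "mw"))),
               class = "mlcqsar_schema_error", regexp = "nonexistent")
  m <- fit_mlr(tab, paper_spec("Eq3"))
  bare <- tab; bare$descriptors$log_km <- NULL
  expect_error(predict(m, bare), class = "mlcqsar_schema_error",
               regexp = "log_km")
})

test_that("model specifications validate their fields", {
  expect_error(model_spec("log_Kp", character()), class = "mlcqsar_spec_error")
  expect_error(model_spec("log_Kp", c("mw", "mw")),
               class = "mlcqsar_spec_error")
  expect_error(model_spec("mw", c("mw", "tpsa")),
               class = "mlcqsar_spec_error")
  specs <- paper_model_specs()
  expect_length(specs, 20L)
  expect_equal(specs$Eq9$predictors, c("log_km", "tpsa", "alpha"))
  expect_equal(specs$Eq22$response, "fu_brain")
})

test_that("missing response cells are excluded listwise", {
  z <- tab
  z$compounds$log_Kp[c(3, 8)] <- NA
  m <- fit_mlr(z, paper_spec("Eq3"))
  expect_equal(m$n, 17L)
  expect_false(any(c("3", "8") %in% names(m$fitted)))
})
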