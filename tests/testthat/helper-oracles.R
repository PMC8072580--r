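# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit normal-equations algebra, generic
# optimisation, and brute-force leave-one-out refitting.

# OLS by explicit normal equations (pseudo-inverse style solve).
ols_pinv <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  XtX <- crossprod(X1)
  beta <- solve(XtX, crossprod(X1, y))
  res <- y - X1 %*% beta
  dfree <- nrow(X1) - ncol(X1)
  sigma2 <- sum(res^2) / dfree
  list(coef = drop(beta), se = sqrt(diag(sigma2 * solve(XtX))),
       sigma = sqrt(sigma2))
}

# Transformed-scale Foley parameters via a generic least-squares minimiser.
foley_optim <- function(x, k) {
  obj <- function(par) sum((1 / k - par[1] - par[2] * x)^2)
  fit <- optim(c(mean(1 / k), 0), obj, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 5000))
  c(intercept = fit$par[1], slope = fit$par[2])
}

# PRESS by explicitly refitting the model n times without observation i.
press_refit <- function(frame, response, predictors) {
  fml <- stats::reformulate(predictors, response = response)
  sum(vapply(seq_len(nrow(frame)), function(i) {
    fit <- lm(fml, data = frame[-i, ])
    (frame[[response]][i] -
       predict(fit, newdata = frame[i, , drop = FALSE]))^2
  }, numeric(1)))
}

# Hat-matrix diagonal from the explicit projection matrix.
hat_explicit <- function(X) {
  X1 <- cbind(1, as.matrix(X))
  diag(X1 %*% solve(crossprod(X1)) %*% t(X1))
}

# Two columns with an exact prescribed sample correlation: the second is a
# mix of the standardized first column and a standardized orthogonal
# residual, so cor(x1, x2) = r holds exactly, not just in expectation.
correlated_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  e <- residuals(lm(rnorm(n) ~ x1))
  x1s <- scale(x1)[, 1]
  data.frame(x1 = x1s, x2 = r * x1s + sqrt(1 - r^2) * scale(e)[, 1])
}

# Small synthetic compound table with an exactly linear response.
noiseless_table <- function(n = 12, seed = 42) {
  tr <- mlcqsar::qsar_truth(n_compounds = n, noise_sd = 0, seed = seed)
  mlcqsar::gen_qsar_table(tr)
}

paper_spec <- function(label) mlcqsar::paper_model_specs()[[label]]

# Foley fit that degrades to NA fields instead of erroring, so column-wide
# comparisons can report which compounds failed.
fit_foley_all_or_na <- function(tab, id) {
  mlcqsar::fit_foley(mlcqsar::retention_series(tab, id), on_degenerate = "na")
}
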