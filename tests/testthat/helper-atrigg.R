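# Shared fixtures and independent oracles for the test suite.

# Small, fast dataset for pipeline-level tests.
small_dataset <- function(n = 30, seed = 101, ...) {
  simulate_dataset(sim_config(n_samples = n, seed = seed, ...))
}

# Brute-force Savitzky-Golay oracle: per output point, an explicit local
# polynomial least-squares fit over the mirror-padded window, evaluated
# (or differentiated) at the window centre. Independent of the package's
# convolution implementation.
sg_oracle <- function(x, window, polyorder, deriv = 0, spacing = 1) {
  n <- length(x)
  h <- (window - 1) / 2
  xp <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
  pos <- (-h:h) * (-spacing)          # wavenumber offsets, descending grid
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- xp[i:(i + window - 1)]
    fit <- stats::lm.fit(outer(pos, 0:polyorder, `^`), win)
    out[i] <- fit$coefficients[deriv + 1] * factorial(deriv)
  }
  out
}

# Least-squares oracle: minimum-norm OLS predictions on centred data.
ols_oracle_predictions <- function(X, y) {
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  beta <- qr.coef(qr(Xc), y - mean(y))
  beta[is.na(beta)] <- 0
  mean(y) + drop(Xc %*% beta)
}
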