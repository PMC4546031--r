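test_that("PLS1 base cases: mean-only model, rank-1 exactness, toy prediction", {
  set.seed(2)
  X <- matrix(rnorm(8 * 5), 8, 5)
  y <- rnorm(8, 100, 10)

  m0 <- fit_pls1(X, y, 0)
  expect_equal(predict(m0, X), rep(mean(y), 8))

  # y exactly proportional to one spectral direction: one factor suffices
  dirv <- rnorm(5)
  conc <- runif(8, 1, 3)
  X1 <- outer(conc, dirv)
  y1 <- 250 * conc
  m1 <- fit_pls1(X1, y1, 1)
  expect_equal(predict(m1, X1), y1, tolerance = 1e-8)

  # hand-computed affine prediction on a 3x4 toy
  m <- fit_pls1(matrix(rnorm(12), 3, 4), c(1, 2, 3), 1)
  xnew <- rnorm(4)
  expect_equal(predict(m, xnew),
               m$intercept + sum(xnew * m$coefficients), tolerance = 1e-12)

  # predicting the training mean spectrum returns the training mean response
  expect_equal(predict(m1, m1$x_mean), m1$y_mean, tolerance = 1e-8)

  expect_error(fit_pls1(X, y, 20), "0..min")
  expect_error(fit_pls1(X, rep(1, 8), 2), "constant")
})

test_that("full-rank PLS1 equals the least-squares oracle (50 random problems)", {
  set.seed(10)
  for (i in 1:50) {
    X <- matrix(rnorm(10 * 6), 10, 6)
    y <- rnorm(10)
    m <- fit_pls1(X, y, 6)
    expect_equal(predict(m, X), ols_oracle_predictions(X, y),
                 tolerance = 1e-8)
  }
})

test_that("score vectors are orthogonal and training error non-increasing in k", {
  set.seed(4)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- X %*% rnorm(12) + rnorm(30, sd = 0.1)
  m <- fit_pls1(X, y, 8)
  Tm <- attr(m, "scores")
  G <- crossprod(Tm)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)

  rmsec <- vapply(0:8, function(k) rmse(y, predict(fit_pls1(X, y, k), X)),
                  numeric(1))
  expect_true(all(diff(rmsec) < 1e-10))

  # prediction is affine: interpolation commutes with prediction
  x1 <- rnorm(12); x2 <- rnorm(12); a <- 0.3
  expect_equal(predict(m, a * x1 + (1 - a) * x2),
               a * predict(m, x1) + (1 - a) * predict(m, x2),
               tolerance = 1e-10)
})

test_that("per-factor validation predictions match the regression-vector route", {
  set.seed(6)
  X <- matrix(rnorm(25 * 10), 25, 10)
  y <- X %*% rnorm(10) + rnorm(25)
  fit <- fit_pls1(X[1:18, ], y[1:18], 6)
  all_k <- atrigg:::predict_all_factors(fit, X[19:25, ])
  for (k in 1:6) {
    mk <- fit_pls1(X[1:18, ], y[1:18], k)
    expect_equal(all_k[, k], unname(predict(mk, X[19:25, ])),
                 tolerance = 1e-8)
  }
})

test_that("Monte Carlo CV recovers the latent dimension and is reproducible", {
  # noiseless rank-1 problem: one factor is optimal
  set.seed(3)
  dirv <- rnorm(25)
  conc <- runif(40, 0.1, 3)
  X <- outer(conc, dirv)
  y <- 1000 * conc
  sel <- mccv_select_factors(X, y, k_max = 5, n_repeats = 200, seed = 7)
  expect_equal(sel$chosen_k, 1L)
  expect_true(all(sel$rmmccv >= 0))

  # 3-component simulator data at high signal-to-noise
  ds <- small_dataset(n = 40, seed = 17, noise_sd = 1e-4, scatter_sd = 0,
                      baseline_drift_sd = 0, outlier_rate = 0)
  pp <- atrigg:::preprocess_dataset(ds, pp_preset("smooth"))
  sel3 <- mccv_select_factors(pp$averaged, ds$samples$igg_reference,
                              k_max = 8, n_repeats = 200, seed = 7)
  expect_true(sel3$chosen_k %in% 2:5)
  expect_lt(sel3$rmmccv[sel3$chosen_k], sel3$rmmccv[1])

  # same seed, same curve
  sel3b <- mccv_select_factors(pp$averaged, ds$samples$igg_reference,
                               k_max = 8, n_repeats = 200, seed = 7)
  expect_identical(sel3$rmmccv, sel3b$rmmccv)

  expect_error(mccv_select_factors(X, y, k_max = 50, n_repeats = 5),
               "k_max")
})

test_that("final model refit delegates to a plain PLS1 fit on the pooled set", {
  set.seed(9)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- X %*% rnorm(8) + rnorm(20)
  mf <- fit_final_model(X, y, 3)
  m <- fit_pls1(X, y, 3)
  expect_equal(mf$coefficients, m$coefficients)
  expect_equal(mf$intercept, m$intercept)
  expect_lte(rmse(y, predict(mf, X)), rmse(y, predict(fit_pls1(X, y, 1), X)))
  expect_equal(unname(predict(fit_final_model(X, y, 0), X)),
               rep(mean(y), 20))
})

test_that("model JSON serialization round-trips the prediction state", {
  set.seed(12)
  X <- matrix(rnorm(15 * 6), 15, 6)
  y <- X %*% rnorm(6) + 50
  m <- fit_pls1(X, y, 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f, grid = c(3000, 2000, 1500, 1200, 1000, 800))
  back <- read_model_json(f)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(predict(back, X), predict(m, X), tolerance = 1e-12)
  expect_error(read_model_json(withr::local_tempfile(lines = "{}",
                                                     fileext = ".json")),
               "pls1_model")
})
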