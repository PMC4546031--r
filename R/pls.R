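# PLS1 regression by classical NIPALS with deflation of both X and y.
# X is mean-centred only (no column scaling: spectra are normalized as
# spectra, not per wavenumber). Predictions are affine, yhat = b0 + x.b,
# and at k = rank(Xc) coincide with the least-squares solution.

#' Fit a single-response PLS regression model (NIPALS)
#'
#' Per factor: `w = X'y / ||X'y||`, `t = Xw`, `p = X't/(t't)`,
#' `q = y't/(t't)`, then X and y are deflated. The regression vector is
#' `b = W (P'W)^-1 q` with intercept `b0 = mean(y) - mean(x).b`. If the
#' residual signal vanishes before `k` factors, the model is truncated to
#' the extractable number of factors.
#'
#' @param X Numeric matrix, samples in rows, spectral points in columns.
#' @param y Response vector (IgG, mg/dL).
#' @param k Number of latent factors, `0 <= k <= min(n-1, p)`; `k = 0`
#'   gives the mean-only model.
#' @return A list of class `pls1_model`: `n_factors`, `x_mean`, `y_mean`,
#'   `weights` (p x k), `x_loadings` (p x k), `y_loadings` (k),
#'   `coefficients` (b), `intercept` (b0), `scores` (n x k).
#' @export
fit_pls1 <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L || length(y) != n) {
    stop("`X` needs >= 2 rows and `y` must match its row count")
  }
  if (k < 0 || k > min(n - 1, p)) {
    stop("`k` must lie in 0..min(n-1, p)")
  }
  if (k > 0 && stats::var(y) == 0) {
    stop("`y` is constant; no factor can be extracted")
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean

  W <- P <- matrix(0, p, k)
  q <- numeric(k)
  Tm <- matrix(0, n, k)
  k_eff <- 0L
  nw2_ref <- tt_ref <- NA_real_
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xc, yc))
    nw2 <- sum(w^2)
    # stop when the residual covariance or score energy is numerically
    # exhausted relative to the first factor (rank reached)
    if (a == 1L) nw2_ref <- nw2
    if (nw2 == 0 || nw2 <= 1e-24 * nw2_ref) break
    w <- w / sqrt(nw2)
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    if (a == 1L) tt_ref <- tt
    if (tt == 0 || tt <= 1e-24 * tt_ref) break
    p_ <- drop(crossprod(Xc, t_)) / tt
    q_ <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - q_ * t_
    W[, a] <- w; P[, a] <- p_; q[a] <- q_; Tm[, a] <- t_
    k_eff <- a
  }
  W <- W[, seq_len(k_eff), drop = FALSE]
  P <- P[, seq_len(k_eff), drop = FALSE]
  q <- q[seq_len(k_eff)]
  Tm <- Tm[, seq_len(k_eff), drop = FALSE]

  b <- if (k_eff == 0L) numeric(p) else
    drop(W %*% solve(crossprod(P, W), q))
  structure(list(n_factors = k_eff, x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = q,
                 coefficients = b, intercept = y_mean - sum(x_mean * b)),
            class = "pls1_model", scores = Tm)
}

#' Predict IgG concentrations from a fitted PLS1 model
#'
#' @param object A `pls1_model`.
#' @param newdata Numeric matrix (or single spectrum vector) with the same
#'   number of spectral points the model was trained on.
#' @param ... Unused.
#' @return Numeric vector of predictions, `b0 + X b`.
#' @export
predict.pls1_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("`newdata` column count does not match the trained model")
  }
  drop(newdata %*% object$coefficients) + object$intercept
}

# Validation predictions for every factor count 1..n_factors in one pass,
# via score-space deflation of the new data (equivalent to the b_k route).
# Returns an m x n_factors matrix. Used by the Monte Carlo CV loop.
predict_all_factors <- function(model, newdata) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  k <- model$n_factors
  m <- nrow(newdata)
  out <- matrix(model$y_mean, m, max(k, 1L))
  if (k == 0L) return(out)
  Xc <- sweep(newdata, 2, model$x_mean)
  acc <- rep(model$y_mean, m)
  for (a in seq_len(k)) {
    t_ <- drop(Xc %*% model$weights[, a])
    acc <- acc + model$y_loadings[a] * t_
    out[, a] <- acc
    Xc <- Xc - tcrossprod(t_, model$x_loadings[, a])
  }
  out
}

#' Refit the final calibration model on the full calibration set
#'
#' Once the number of latent factors has been selected by
#' [mccv_select_factors()], the training and validation samples are pooled
#' and a single PLS1 model is fitted with that factor count.
#'
#' @param X_cal,y_cal Full calibration set.
#' @param chosen_k Selected factor count.
#' @return A `pls1_model`.
#' @export
fit_final_model <- function(X_cal, y_cal, chosen_k) {
  fit_pls1(X_cal, y_cal, chosen_k)
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("PLS1 calibration model: %d latent factor(s), %d spectral points\n",
              x$n_factors, length(x$x_mean)))
  cat(sprintf("intercept b0 = %.4g mg/dL\n", x$intercept))
  invisible(x)
}

#' Serialize / restore a PLS1 model as JSON
#'
#' Stores the grid, centring statistics, regression vector and factor
#' count in one JSON document so a trained calibration can be shipped as a
#' plain-text artifact.
#'
#' @param model A `pls1_model`.
#' @param path Destination (for write) or source (for read) file path.
#' @param grid Optional wavenumber grid to embed.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a `pls1_model` (prediction state only).
#' @export
write_model_json <- function(model, path, grid = NULL) {
  doc <- list(
    type = "pls1_model", n_factors = model$n_factors,
    x_mean = model$x_mean, y_mean = model$y_mean,
    coefficients = model$coefficients, intercept = model$intercept,
    grid = if (is.null(grid)) NULL else as.numeric(grid)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "pls1_model")) stop("not a pls1_model JSON file")
  structure(list(n_factors = doc$n_factors, x_mean = doc$x_mean,
                 y_mean = doc$y_mean, weights = NULL, x_loadings = NULL,
                 y_loadings = NULL, coefficients = doc$coefficients,
                 intercept = doc$intercept, grid = doc$grid),
            class = "pls1_model")
}
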