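# Monte Carlo cross-validation for choosing the number of PLS factors.
#
# Each repeat draws a fresh random train/validation split of the
# calibration set, fits PLS1 on the training half (centring recomputed per
# split) and accumulates squared validation errors for every factor count.
# RMMCCV_k = sqrt(total squared error at k / (n_repeats * validation_size));
# the chosen factor count is the smallest k attaining the minimum.

#' Select the number of PLS factors by Monte Carlo cross-validation
#'
#' @param X_cal Calibration spectra matrix (samples x points).
#' @param y_cal Reference IgG concentrations (mg/dL).
#' @param k_max Largest factor count tried (default 30).
#' @param n_repeats Number of random splits (default 10000; a few hundred
#'   already give a stable minimum on desk-scale problems).
#' @param train_size Training-set size per split; default
#'   `ceiling(n / 2)` (67 of a 133-sample calibration set, leaving 66 for
#'   validation).
#' @param seed Integer seed; splits are reproducible given it.
#' @return A list of class `mccv_result`: `rmmccv` (vector over
#'   k = 1..k_max, mg/dL), `chosen_k`, `k_max`, `n_repeats`, `train_size`,
#'   `validation_size`, `seed`.
#' @export
mccv_select_factors <- function(X_cal, y_cal, k_max = 30, n_repeats = 10000,
                                train_size = NULL, seed = 1) {
  X_cal <- as.matrix(X_cal)
  y_cal <- as.numeric(y_cal)
  n <- nrow(X_cal)
  if (is.null(train_size)) train_size <- ceiling(n / 2)
  val_size <- n - train_size
  if (train_size < 2 || val_size < 1) {
    stop("`train_size` must leave at least 2 training and 1 validation sample")
  }
  if (k_max < 1 || k_max > min(train_size - 1, ncol(X_cal))) {
    stop("`k_max` must lie in 1..min(train_size-1, ncol(X_cal))")
  }
  sse <- numeric(k_max)
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      tr <- sample.int(n, train_size)
      fit <- fit_pls1(X_cal[tr, , drop = FALSE], y_cal[tr], k_max)
      pred <- predict_all_factors(fit, X_cal[-tr, , drop = FALSE])
      err2 <- (y_cal[-tr] - pred)^2
      cs <- colSums(err2)
      # if the fit truncated below k_max, higher k inherit the last column
      if (length(cs) < k_max) {
        cs <- c(cs, rep(cs[length(cs)], k_max - length(cs)))
      }
      sse <- sse + cs
    }
  })
  rmmccv <- sqrt(sse / (n_repeats * val_size))
  structure(list(rmmccv = rmmccv, chosen_k = which.min(rmmccv),
                 k_max = k_max, n_repeats = n_repeats,
                 train_size = train_size, validation_size = val_size,
                 seed = seed),
            class = "mccv_result")
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Monte Carlo CV: %d repeats, %d/%d train/validation split\n",
    "chosen number of PLS factors: %d (RMMCCV %.4g mg/dL)\n"),
    x$n_repeats, x$train_size, x$validation_size, x$chosen_k,
    x$rmmccv[x$chosen_k]))
  invisible(x)
}

#' @export
as.data.frame.mccv_result <- function(x, ...) {
  data.frame(k = seq_along(x$rmmccv), rmmccv = x$rmmccv)
}
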