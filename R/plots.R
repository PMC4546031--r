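# Optional diagnostic figures (ggplot2 is suggested, not required).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("install 'ggplot2' to draw the diagnostic figures")
  }
}

#' Reference-vs-predicted agreement scatter plot
#'
#' @param run An `atr_run` from [run_full()].
#' @return A ggplot object: calibration and prediction samples against the
#'   identity line.
#' @export
plot_agreement <- function(run) {
  need_ggplot()
  df <- data.frame(
    reference = c(run$calibration$reference, run$prediction$reference),
    predicted = c(run$calibration$predicted, run$prediction$predicted),
    set = rep(c("calibration", "prediction"),
              c(length(run$calibration$reference),
                length(run$prediction$reference))))
  ggplot2::ggplot(df, ggplot2::aes(reference, predicted,
                                   shape = set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "RID reference IgG (mg/dL)",
                  y = "ATR predicted IgG (mg/dL)", shape = NULL)
}

#' Bland-Altman plot for the prediction set
#'
#' @param run An `atr_run`.
#' @return A ggplot object: per-sample differences against means, with the
#'   mean difference and 95% limits of agreement.
#' @export
plot_bland_altman <- function(run) {
  need_ggplot()
  ba <- run$prediction$agreement$bland_altman
  df <- data.frame(
    avg = (run$prediction$reference + run$prediction$predicted) / 2,
    diff = run$prediction$predicted - run$prediction$reference)
  ggplot2::ggplot(df, ggplot2::aes(avg, diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$mean_diff) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of methods (mg/dL)",
                  y = "ATR - RID difference (mg/dL)")
}

#' RMMCCV-versus-factor-count curve
#'
#' @param mccv An `mccv_result` (or an `atr_run`).
#' @return A ggplot object with the chosen factor count marked.
#' @export
plot_mccv <- function(mccv) {
  need_ggplot()
  if (inherits(mccv, "atr_run")) mccv <- mccv$mccv
  df <- as.data.frame(mccv)
  ggplot2::ggplot(df, ggplot2::aes(k, rmmccv)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = mccv$chosen_k, linetype = 2) +
    ggplot2::labs(x = "Number of PLS factors", y = "RMMCCV (mg/dL)")
}
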