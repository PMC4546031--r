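# Agreement and diagnostic statistics: RMSE family, Pearson r, Lin's
# concordance correlation, Bland-Altman limits of agreement, modified CV*,
# RPD/RER with their conventional interpretation bands, and the 2x2
# diagnostic table for failure of transfer of passive immunity (FTPI).

#' Root mean squared error
#'
#' @param reference,predicted Equal-length numeric vectors (mg/dL).
#' @return `sqrt(mean((predicted - reference)^2))`.
#' @export
rmse <- function(reference, predicted) {
  if (length(reference) == 0L || length(reference) != length(predicted)) {
    stop("`reference` and `predicted` must be equal-length, non-empty")
  }
  sqrt(mean((predicted - reference)^2))
}

#' Pearson product-moment correlation
#'
#' Thin, validated wrapper over [stats::cor()].
#'
#' @param x,y Equal-length numeric vectors, length >= 2, both non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) < 2L || length(x) != length(y)) {
    stop("`x` and `y` must be equal-length with >= 2 values")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("Pearson correlation is undefined for a constant vector")
  }
  stats::cor(x, y)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments, penalizing both dispersion and location shift between two
#' measurement methods. Always `|CCC| <= |r|`.
#'
#' @param x,y Equal-length numeric vectors, length >= 2.
#' @return Concordance correlation in `[-1, 1]`.
#' @export
concordance_ccc <- function(x, y) {
  if (length(x) < 2L || length(x) != length(y)) {
    stop("`x` and `y` must be equal-length with >= 2 values")
  }
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) stop("CCC is undefined: both inputs constant and equal")
  2 * sxy / denom
}

#' Bland-Altman limits of agreement
#'
#' Differences are taken as `test - reference`; the limits are
#' `mean(d) +/- 1.96 * sd(d)` with the sample (n-1) SD.
#'
#' @param reference Reference-method values (mg/dL).
#' @param test Test-method values (mg/dL).
#' @return List: `mean_diff`, `loa_low`, `loa_high`, `sd_diff`,
#'   `differences`.
#' @export
bland_altman <- function(reference, test) {
  if (length(reference) < 2L || length(reference) != length(test)) {
    stop("`reference` and `test` must be equal-length with >= 2 values")
  }
  d <- test - reference
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       sd_diff = s, differences = d)
}

#' Modified coefficient of variation for replicate measurements
#'
#' `CV = sd/mean` (sample SD) with the small-sample correction
#' `CV* = CV (1 + 1/(4n))`, n the replicate count.
#'
#' @param replicate_values Replicate measurements of one sample
#'   (length >= 2, non-zero mean).
#' @return List: `n`, `mean`, `sd`, `cv`, `cv_star`.
#' @export
cv_star <- function(replicate_values) {
  n <- length(replicate_values)
  if (n < 2L) stop("CV* needs at least 2 replicates")
  m <- mean(replicate_values)
  if (m == 0) stop("CV* is undefined for a zero mean")
  s <- stats::sd(replicate_values)
  cv <- s / m
  list(n = n, mean = m, sd = s, cv = cv, cv_star = cv * (1 + 1 / (4 * n)))
}

#' Ratio of predictive deviation and range error ratio
#'
#' `RPD = SD(reference) / RMSEP` and `RER = range(reference) / RMSEP`, with
#' the conventional interpretation bands: RPD < 2 poorly predictive;
#' 2-2.5 adequate for screening; > 2.5 (or RER > 10) acceptable for
#' quantification; > 3 (or RER > 20) suitable for accurate quantitative
#' analysis.
#'
#' @param sd_reference Population SD of the reference concentrations
#'   (mg/dL).
#' @param range_reference Range (max - min) of the reference concentrations
#'   (mg/dL).
#' @param rmsep Root mean squared error of prediction (mg/dL).
#' @return List: `rpd`, `rer`, `interpretation`.
#' @examples
#' rpd_rer(876, 2977, 326)   # RPD 2.7, RER 9.1
#' @export
rpd_rer <- function(sd_reference, range_reference, rmsep) {
  vals <- c(sd_reference, range_reference, rmsep)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all of `sd_reference`, `range_reference`, `rmsep` must be > 0")
  }
  rpd <- sd_reference / rmsep
  rer <- range_reference / rmsep
  interpretation <-
    if (rpd > 3 || rer > 20) "accurate quantification"
    else if (rpd > 2.5 || rer > 10) "quantification"
    else if (rpd >= 2) "screening"
    else "poor"
  list(rpd = rpd, rer = rer, interpretation = interpretation)
}

#' Classify a sample as FTPI-positive
#'
#' Failure of transfer of passive immunity is defined as serum IgG strictly
#' below the cut-off (default 1000 mg/dL).
#'
#' @param igg IgG concentration(s), mg/dL, non-negative.
#' @param cutoff Diagnostic cut-off, mg/dL.
#' @return Logical vector, `TRUE` where `igg < cutoff`.
#' @export
classify_ftpi <- function(igg, cutoff = 1000) {
  if (any(igg < 0, na.rm = TRUE)) stop("IgG concentrations must be >= 0")
  igg < cutoff
}

#' 2x2 diagnostic table for FTPI detection
#'
#' A sample is condition-positive when the reference method reads below the
#' cut-off and test-positive when the predicted value does. Negative
#' predicted concentrations (possible near zero for an affine calibration)
#' are clamped to 0 before classification. Undefined rates (zero
#' denominators) are reported as `NA`, never as zero.
#'
#' @param reference Reference IgG values (mg/dL).
#' @param predicted Predicted IgG values (mg/dL).
#' @param cutoff FTPI cut-off, mg/dL (default 1000).
#' @return List of class `diagnostic_table`: counts `tp`, `fp`, `tn`, `fn`,
#'   `n`; rates `sensitivity`, `specificity`, `accuracy`,
#'   `true_prevalence`, `apparent_prevalence`; and `cutoff`.
#' @export
diagnostic_table <- function(reference, predicted, cutoff = 1000) {
  if (length(reference) < 1L || length(reference) != length(predicted)) {
    stop("`reference` and `predicted` must be equal-length, non-empty")
  }
  ref_pos <- classify_ftpi(reference, cutoff)
  test_pos <- classify_ftpi(pmax(predicted, 0), cutoff)
  tp <- sum(ref_pos & test_pos)
  fp <- sum(!ref_pos & test_pos)
  tn <- sum(!ref_pos & !test_pos)
  fn <- sum(ref_pos & !test_pos)
  n <- length(reference)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    accuracy = (tp + tn) / n,
    true_prevalence = (tp + fn) / n,
    apparent_prevalence = (tp + fp) / n,
    cutoff = cutoff
  ), class = "diagnostic_table")
}

#' @export
print.diagnostic_table <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.0f%%", 100 * v)
  cat(sprintf(paste0(
    "FTPI diagnostic table (cut-off %g mg/dL, n = %d)\n",
    "  TP %d  FP %d  TN %d  FN %d\n",
    "  Se %s  Sp %s  accuracy %s\n",
    "  prevalence: true %s, apparent %s\n"),
    x$cutoff, x$n, x$tp, x$fp, x$tn, x$fn,
    pct(x$sensitivity), pct(x$specificity), pct(x$accuracy),
    pct(x$true_prevalence), pct(x$apparent_prevalence)))
  invisible(x)
}

#' Agreement metrics between reference and predicted concentrations
#'
#' Bundles the evaluation of one sample set: RMSE, Pearson r, Lin's CCC,
#' Bland-Altman limits of agreement, and (using the reference values' own
#' population SD and range) RPD and RER.
#'
#' @param reference,predicted Equal-length vectors (mg/dL), length >= 2.
#' @return List of class `agreement_report`: `n`, `rmse`, `pearson_r`,
#'   `ccc`, `bland_altman`, `rpd`, `rer`, `rpd_interpretation`,
#'   `sd_reference` (population), `range_reference`.
#' @export
evaluate_agreement <- function(reference, predicted) {
  n <- length(reference)
  sd_pop <- sqrt(mean((reference - mean(reference))^2))
  rng <- max(reference) - min(reference)
  err <- rmse(reference, predicted)
  rr <- rpd_rer(sd_pop, rng, err)
  structure(list(
    n = n, rmse = err,
    pearson_r = pearson(reference, predicted),
    ccc = concordance_ccc(reference, predicted),
    bland_altman = bland_altman(reference, predicted),
    rpd = rr$rpd, rer = rr$rer, rpd_interpretation = rr$interpretation,
    sd_reference = sd_pop, range_reference = rng
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Agreement over %d samples\n",
    "  RMSE %.4g mg/dL;  Pearson r %.3f;  CCC %.3f\n",
    "  Bland-Altman: mean diff %.4g mg/dL, LoA [%.4g, %.4g]\n",
    "  RPD %.2f, RER %.2f (%s)\n"),
    x$n, x$rmse, x$pearson_r, x$ccc,
    x$bland_altman$mean_diff, x$bland_altman$loa_low, x$bland_altman$loa_high,
    x$rpd, x$rer, x$rpd_interpretation))
  invisible(x)
}
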