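# Savitzky-Golay filtering: local least-squares polynomial smoothing and
# differentiation, applied by convolution with mirror padding so output
# length equals input length.

# Convolution coefficients for the fitted value (deriv = 0) or the
# derivative with respect to increasing wavenumber (deriv = 1, 2) at the
# window centre. The grid is stored descending, so one index step moves
# -spacing in wavenumber; building the local abscissa with that sign makes
# derivative signs follow the physical (increasing-wavenumber) convention
# regardless of storage order.
savgol_coefficients <- function(window, polyorder, deriv = 0, spacing = 1) {
  if (window %% 2 == 0) stop("`window` must be odd")
  if (polyorder < 0 || window < polyorder + 2) {
    stop("`window` must be >= polyorder + 2")
  }
  if (deriv > polyorder) stop("derivative order must be <= polyorder")
  h <- (window - 1) / 2
  x <- (-h:h) * (-spacing)
  A <- outer(x, 0:polyorder, `^`)
  C <- solve(crossprod(A), t(A))       # (polyorder+1) x window
  C[deriv + 1, ] * factorial(deriv)
}

savgol_apply <- function(values, coef) {
  n <- length(values)
  w <- length(coef)
  h <- (w - 1) / 2
  if (n < w) stop("`window` must not exceed the signal length")
  xp <- c(values[(h + 1):2], values, values[(n - 1):(n - h)])  # mirror pad
  out <- numeric(n)
  for (j in seq_len(w)) out <- out + coef[j] * xp[j:(j + n - 1)]
  out
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the value of a local least-squares polynomial fit
#' over a sliding window. Ends are mirror-padded so the output has the same
#' length as the input; any polynomial of degree <= `polyorder` is
#' reproduced exactly at interior points.
#'
#' @param values Numeric vector (one spectrum).
#' @param window Odd window length in points (default 9).
#' @param polyorder Polynomial degree (default 2).
#' @return Smoothed vector of the same length.
#' @export
savgol_smooth <- function(values, window = 9, polyorder = 2) {
  savgol_apply(values, savgol_coefficients(window, polyorder, deriv = 0))
}

#' Savitzky-Golay derivative
#'
#' First or second derivative with respect to wavenumber, computed by
#' Savitzky-Golay convolution (so differentiation and smoothing happen in
#' one pass). The derivative is taken with respect to *increasing*
#' wavenumber even though spectra are stored in descending order.
#'
#' @param values Numeric vector (one spectrum).
#' @param order Derivative order, 1 or 2.
#' @param window Odd window length in points (default 9).
#' @param polyorder Polynomial degree of the local fit (default 2).
#' @param spacing Grid spacing in cm^-1 per point (default 1, giving
#'   derivatives per index step).
#' @return Derivative vector of the same length, in AU.cm (order 1) or
#'   AU.cm^2 (order 2).
#' @export
savgol_derivative <- function(values, order, window = 9, polyorder = 2,
                              spacing = 1) {
  if (!order %in% c(1, 2)) stop("`order` must be 1 or 2")
  savgol_apply(values,
               savgol_coefficients(window, polyorder, deriv = order,
                                   spacing = spacing))
}
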