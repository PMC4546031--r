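# Wavenumber grid: the shared x-axis for every spectrum in a dataset.
# Stored in descending order (spectroscopy convention, high wavenumber left).

#' Construct the default mid-infrared wavenumber grid
#'
#' Builds the descending wavenumber grid used by the ATR assay: 4000 cm^-1
#' down to 650 cm^-1 at a constant point spacing. If the spacing does not
#' divide the 4000-650 span exactly, a final point clamped to 650 cm^-1 is
#' appended so the grid always reaches the fingerprint-region edge.
#'
#' The instrument's nominal optical resolution (8 cm^-1) is coarser than the
#' default digitization spacing of 4 cm^-1 per point, as is usual for FTIR
#' interferogram zero-filling.
#'
#' @param spacing Point spacing in cm^-1; a single positive number.
#' @return A numeric vector of class `wn_grid`, strictly descending from 4000
#'   to 650 cm^-1, with a `spacing` attribute.
#' @examples
#' g <- make_default_grid(8)
#' length(g)   # 420 points: 4000, 3992, ..., 656, then 650 clamped
#' range(g)
#' @export
make_default_grid <- function(spacing = 4) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop("`spacing` must be a single positive number of cm^-1 per point")
  }
  wn <- seq(4000, 650, by = -spacing)
  if (wn[length(wn)] > 650) wn <- c(wn, 650)
  structure(wn, class = "wn_grid", spacing = spacing)
}

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("Wavenumber grid: %d points, %.6g to %.6g cm^-1 (spacing %g)\n",
              length(x), x[1], x[length(x)], attr(x, "spacing")))
  invisible(x)
}

# Internal validator shared by the simulator and the preprocessing chain.
assert_grid <- function(grid) {
  g <- as.numeric(grid)
  if (length(g) < 2L || anyNA(g) || any(!is.finite(g))) {
    stop("wavenumber grid must hold at least 2 finite values")
  }
  d <- diff(g)
  if (any(d >= 0)) stop("wavenumber grid must be strictly descending")
  invisible(g)
}
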