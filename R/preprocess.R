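# Spectral pre-processing chain: smoothing/derivative -> normalization ->
# region selection -> per-wavenumber Dixon Q-test replicate screen ->
# replicate averaging. Entirely deterministic.

#' Standard normal variate transform
#'
#' Centers one spectrum to mean 0 and scales it to sample (n-1) standard
#' deviation 1, correcting additive offsets and multiplicative scatter
#' (e.g. film-thickness differences between replicates).
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Transformed vector with mean 0 and sample SD 1.
#' @export
snv <- function(values) {
  if (length(values) < 2L) stop("SNV needs at least 2 points")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("SNV is undefined for a constant spectrum")
  (values - mean(values)) / s
}

#' Euclidean vector normalization
#'
#' Scales a spectrum to unit Euclidean norm, preserving direction (and
#' sign), correcting multiplicative scatter but not additive offsets.
#'
#' @param values Numeric vector with non-zero norm.
#' @return Vector with Euclidean norm 1.
#' @export
vector_normalize <- function(values) {
  nrm <- sqrt(sum(values^2))
  if (!is.finite(nrm) || nrm == 0) {
    stop("vector normalization is undefined for the zero vector")
  }
  values / nrm
}

#' Select wavenumber regions
#'
#' Restricts a spectrum (or a matrix of spectra, one per row) to the points
#' whose wavenumber falls in any of the given closed intervals. Output
#' order preserves the descending grid, highest region first.
#'
#' @param grid Descending wavenumber grid.
#' @param values Numeric vector aligned with `grid`, or a matrix with
#'   `length(grid)` columns; may be `NULL` to get the index set only.
#' @param regions List of `(high, low)` cm^-1 interval pairs; default the
#'   protein-band windows 3700-2600 and 1800-1300 cm^-1.
#' @return List with `grid` (sub-grid), `values` (sub-vector/matrix or
#'   `NULL`) and `idx` (selected column indices).
#' @export
select_regions <- function(grid, values = NULL,
                           regions = list(c(3700, 2600), c(1800, 1300))) {
  wn <- assert_grid(grid)
  regs <- lapply(regions, function(r) sort(as.numeric(r), decreasing = TRUE))
  regs <- regs[order(vapply(regs, `[`, numeric(1), 1), decreasing = TRUE)]
  idx <- unlist(lapply(regs, function(r) which(wn <= r[1] & wn >= r[2])))
  idx <- unique(idx)
  if (length(idx) == 0L) {
    stop("no grid point falls inside the requested region(s)")
  }
  sub <- NULL
  if (!is.null(values)) {
    sub <- if (is.matrix(values)) values[, idx, drop = FALSE] else values[idx]
  }
  list(grid = wn[idx], values = sub, idx = idx)
}

# Two-sided critical values for Dixon's r10 ("Q") statistic, n = 3..7.
dixon_critical_table <- rbind(
  `3` = c(`0.9` = 0.941, `0.95` = 0.970, `0.99` = 0.994),
  `4` = c(0.765, 0.829, 0.926),
  `5` = c(0.642, 0.710, 0.821),
  `6` = c(0.560, 0.625, 0.740),
  `7` = c(0.507, 0.568, 0.680)
)

dixon_critical <- function(n, confidence = 0.95) {
  if (n < 3 || n > 7) stop("Dixon's Q test is tabulated for n = 3..7 only")
  col <- match(as.character(confidence), colnames(dixon_critical_table))
  if (is.na(col)) {
    stop("`confidence` must be one of 0.90, 0.95, 0.99")
  }
  dixon_critical_table[as.character(n), col]
}

#' Dixon's Q test for a single outlier
#'
#' Computes the r10 ("gap over range") statistic at both extremes of a
#' small sample: `q_low = (x(2)-x(1))/(x(n)-x(1))` and
#' `q_high = (x(n)-x(n-1))/(x(n)-x(1))`. The larger of the two is compared
#' with the tabulated critical value (e.g. 0.710 for n = 5 at 95%
#' confidence); at most one observation is flagged.
#'
#' @param values 3 to 7 numbers.
#' @param confidence One of 0.90, 0.95, 0.99.
#' @return List with `q_low`, `q_high`, `outlier` (index into `values`, or
#'   `NA` if none flagged) and `critical`. A zero range yields undefined
#'   statistics (`NA`) and no outlier.
#' @examples
#' dixon_q(c(1, 2, 3, 4, 100))$outlier   # 5
#' @export
dixon_q <- function(values, confidence = 0.95) {
  n <- length(values)
  crit <- dixon_critical(n, confidence)
  s <- sort(values)
  rng <- s[n] - s[1]
  if (rng == 0) {
    return(list(q_low = NA_real_, q_high = NA_real_,
                outlier = NA_integer_, critical = crit))
  }
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  outlier <- NA_integer_
  if (max(q_low, q_high) > crit) {
    outlier <- if (q_high >= q_low) which.max(values) else which.min(values)
  }
  list(q_low = q_low, q_high = q_high, outlier = outlier, critical = crit)
}

#' Per-wavenumber Dixon screen for whole-replicate outliers
#'
#' Applies [dixon_q()] independently at every wavenumber point across the
#' replicate spectra of one sample. A replicate flagged at more than
#' `threshold` (default 50%) of the points is excluded as a whole-spectrum
#' outlier. Points where all replicates agree exactly (zero range) flag
#' nobody. At least two replicates must survive.
#'
#' @param replicates Numeric matrix, one replicate spectrum per row (3-7
#'   rows), columns aligned on one grid.
#' @param confidence Dixon confidence level (0.90, 0.95 or 0.99).
#' @param threshold Fraction of flagged points above which a replicate is
#'   excluded.
#' @return A data frame (class `outlier_report`) with one row per
#'   replicate: `replicate`, `flagged_fraction`, `excluded`. Attributes
#'   `q_statistic` (per-point max r10) and `flagged_replicate` (per-point
#'   flagged row or `NA`) are retained for audit.
#' @export
flag_outlier_replicates <- function(replicates, confidence = 0.95,
                                    threshold = 0.5) {
  if (!is.matrix(replicates)) replicates <- as.matrix(replicates)
  k <- nrow(replicates)
  p <- ncol(replicates)
  if (k < 3L) stop("the Dixon screen needs at least 3 replicates")
  crit <- dixon_critical(k, confidence)

  S <- apply(replicates, 2, sort, method = "quick")   # k x p sorted columns
  rng <- S[k, ] - S[1, ]
  ok <- rng > 0
  q_low <- q_high <- rep(NA_real_, p)
  q_low[ok] <- (S[2, ok] - S[1, ok]) / rng[ok]
  q_high[ok] <- (S[k, ok] - S[k - 1, ok]) / rng[ok]
  qmax <- pmax(q_low, q_high)

  hit <- which(ok & qmax > crit)
  flagged <- rep(NA_integer_, p)
  if (length(hit) > 0L) {
    imax <- max.col(t(replicates[, hit, drop = FALSE]), ties.method = "first")
    imin <- max.col(-t(replicates[, hit, drop = FALSE]), ties.method = "first")
    flagged[hit] <- ifelse(q_high[hit] >= q_low[hit], imax, imin)
  }
  counts <- tabulate(flagged[!is.na(flagged)], nbins = k)
  fraction <- counts / p
  excluded <- fraction > threshold
  if (sum(!excluded) < 2L) {
    stop("fewer than 2 replicates survive the outlier screen")
  }
  structure(
    data.frame(replicate = seq_len(k), flagged_fraction = fraction,
               excluded = excluded),
    class = c("outlier_report", "data.frame"),
    q_statistic = qmax, flagged_replicate = flagged
  )
}

#' Average the surviving replicate spectra
#'
#' @param replicates Numeric matrix, one replicate per row.
#' @param report An `outlier_report` from [flag_outlier_replicates()], or
#'   `NULL` to average all rows.
#' @return Pointwise arithmetic mean over non-excluded replicates.
#' @export
average_replicates <- function(replicates, report = NULL) {
  if (!is.matrix(replicates)) replicates <- as.matrix(replicates)
  keep <- rep(TRUE, nrow(replicates))
  if (!is.null(report)) keep <- !report$excluded
  if (sum(keep) < 2L) stop("fewer than 2 replicates available to average")
  colMeans(replicates[keep, , drop = FALSE])
}

#' Pre-processing specification
#'
#' Describes one pre-processing variant of the calibration pipeline. The
#' stages run in this order, each applied per replicate before averaging:
#' smoothing *or* derivative, then normalization (on the full-range
#' spectrum), then region selection, then the Dixon replicate screen, then
#' averaging.
#'
#' @param smoothing `"savgol"` or `"none"`. Ignored when a derivative is
#'   requested (the derivative filter smooths in the same pass).
#' @param derivative `"none"`, `"first"` or `"second"`.
#' @param window Savitzky-Golay window, odd, >= `polyorder + 2`.
#' @param polyorder Savitzky-Golay polynomial degree.
#' @param normalization `"none"`, `"snv"` or `"vector"`.
#' @param regions List of `(high, low)` cm^-1 pairs; must not overlap.
#' @param outlier_confidence Dixon confidence level.
#' @param outlier_point_fraction Exclusion threshold on the flagged-point
#'   fraction.
#' @return A list of class `preprocess_spec`.
#' @seealso [pp_preset()] for the nine named variants compared by
#'   [compare_preprocessing()].
#' @export
preprocess_spec <- function(smoothing = c("savgol", "none"),
                            derivative = c("none", "first", "second"),
                            window = 9, polyorder = 2,
                            normalization = c("snv", "none", "vector"),
                            regions = list(c(3700, 2600), c(1800, 1300)),
                            outlier_confidence = 0.95,
                            outlier_point_fraction = 0.5) {
  smoothing <- match.arg(smoothing)
  derivative <- match.arg(derivative)
  normalization <- match.arg(normalization)
  if (window %% 2 == 0 || window < polyorder + 2) {
    stop("`window` must be odd and >= polyorder + 2")
  }
  regs <- lapply(regions, function(r) sort(as.numeric(r)))
  if (length(regs) > 1L) {
    m <- do.call(rbind, regs)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] < m[-nrow(m), 2])) stop("`regions` must not overlap")
  }
  if (!outlier_confidence %in% c(0.9, 0.95, 0.99)) {
    stop("`outlier_confidence` must be one of 0.90, 0.95, 0.99")
  }
  if (outlier_point_fraction <= 0 || outlier_point_fraction >= 1) {
    stop("`outlier_point_fraction` must lie in (0, 1)")
  }
  structure(list(smoothing = smoothing, derivative = derivative,
                 window = window, polyorder = polyorder,
                 normalization = normalization, regions = regions,
                 outlier_confidence = outlier_confidence,
                 outlier_point_fraction = outlier_point_fraction),
            class = "preprocess_spec")
}

#' Named pre-processing presets
#'
#' The nine variants routinely compared for this assay: Savitzky-Golay
#' smoothing or a first/second derivative (9-point window, quadratic),
#' each alone or combined with SNV or vector normalization.
#'
#' @param name One of `pp_presets()`.
#' @return A [preprocess_spec()].
#' @export
pp_preset <- function(name) {
  name <- match.arg(name, pp_presets())
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  base <- parts[1]
  norm <- if (length(parts) > 1) parts[2] else "none"
  preprocess_spec(
    smoothing = if (base == "smooth") "savgol" else "none",
    derivative = switch(base, smooth = "none", d1 = "first", d2 = "second"),
    normalization = norm
  )
}

#' @rdname pp_preset
#' @export
pp_presets <- function() {
  c("smooth", "smooth+snv", "smooth+vector",
    "d1", "d1+snv", "d1+vector",
    "d2", "d2+snv", "d2+vector")
}

#' Run the full pre-processing chain on one sample's replicates
#'
#' Applies, per replicate: (1) Savitzky-Golay smoothing or derivative,
#' (2) normalization on the full-range spectrum, (3) region selection; then
#' (4) the per-wavenumber Dixon screen across replicates, and (5) averaging
#' of the survivors. Deterministic throughout.
#'
#' @param replicates Numeric matrix, one replicate spectrum per row.
#' @param grid Wavenumber grid aligned with the columns.
#' @param spec A [preprocess_spec()].
#' @return List of class `preprocessed_sample`:
#'   `spectrum` (averaged vector), `grid` (selected sub-grid),
#'   `replicates` (processed per-replicate matrix on the sub-grid),
#'   `report` (the `outlier_report`).
#' @export
apply_pipeline <- function(replicates, grid, spec = preprocess_spec()) {
  if (!is.matrix(replicates)) replicates <- matrix(replicates, nrow = 1)
  wn <- assert_grid(grid)
  if (ncol(replicates) != length(wn)) {
    stop("replicate spectra and grid lengths differ")
  }
  spacing <- abs(wn[1] - wn[2])
  step <- function(x) {
    if (spec$derivative != "none") {
      x <- savgol_derivative(x, order = if (spec$derivative == "first") 1 else 2,
                             window = spec$window, polyorder = spec$polyorder,
                             spacing = spacing)
    } else if (spec$smoothing == "savgol") {
      x <- savgol_smooth(x, window = spec$window, polyorder = spec$polyorder)
    }
    switch(spec$normalization, snv = snv(x), vector = vector_normalize(x), x)
  }
  proc <- t(apply(replicates, 1, step))
  sel <- select_regions(wn, proc, regions = spec$regions)
  report <- NULL
  if (nrow(proc) >= 3L) {
    report <- flag_outlier_replicates(sel$values,
                                      confidence = spec$outlier_confidence,
                                      threshold = spec$outlier_point_fraction)
  }
  avg <- if (nrow(proc) == 1L) drop(sel$values) else
    average_replicates(sel$values, report)
  structure(list(spectrum = avg, grid = sel$grid, replicates = sel$values,
                 report = report),
            class = "preprocessed_sample")
}
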