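# Synthetic dried-film serum spectra with known IgG truth.
#
# The generator is a Beer-Lambert mixture model: each replicate spectrum is
#   A(nu) = thickness * sum_i c_i * eps_i(nu) + baseline(nu) + noise(nu)
# with component absorptivities eps_i built from Gaussian bands at the
# positions that dominate real dried-serum ATR spectra (amide A/I/II), a
# lognormal film-thickness factor per replicate, an extra noisy window at
# 2200-1900 cm^-1 (diamond coating of the internal-reflection element), a
# quiet 4000-3800 cm^-1 baseline, and occasional gross whole-replicate
# anomalies flagged in the returned truth.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. All package randomness flows through
# this helper so nothing perturbs (or depends on) global state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

gaussian_band <- function(wn, center, width, height) {
  height * exp(-((wn - center)^2) / (2 * width^2))
}

#' Component absorptivity library for the serum-film mixture model
#'
#' Returns the pure-component absorptivity spectra (absorbance units per
#' g/dL of analyte at unit film thickness) used by [simulate_dataset()].
#' Three components are modelled:
#'
#' * `IgG` - immunoglobulin G; beta-sheet-rich, so its amide I band sits at
#'   1642 cm^-1, with amide II at 1550 cm^-1 and the broad amide A (N-H
#'   stretch) band at 3300 cm^-1.
#' * `albumin` - the dominant serum protein; alpha-helical, amide I at
#'   1656 cm^-1. Same band family as IgG but different relative intensities
#'   and a shifted amide I position, so the two are linearly independent on
#'   the grid.
#' * `matrix` - the non-protein dried-film residue (salts, urea,
#'   carbohydrate); broad weak bands in the fingerprint region.
#'
#' All absorptivities are non-negative and effectively zero above
#' 3800 cm^-1, reproducing the true-baseline character of that region.
#'
#' @param grid A wavenumber grid from [make_default_grid()].
#' @return A named list of numeric vectors (one absorptivity per grid point)
#'   with elements `IgG`, `albumin`, `matrix`.
#' @export
build_component_library <- function(grid) {
  wn <- assert_grid(grid)
  band_sum <- function(bands) {
    Reduce(`+`, lapply(bands, function(b) gaussian_band(wn, b[1], b[2], b[3])))
  }
  # (center cm^-1, width cm^-1, height AU per g/dL)
  igg <- band_sum(list(
    c(3300, 130, 0.050),   # amide A, N-H stretch
    c(2960,  45, 0.010),   # C-H stretch
    c(1642,  26, 0.095),   # amide I, beta-sheet
    c(1550,  22, 0.058),   # amide II
    c(1400,  30, 0.018),
    c(1240,  35, 0.010)
  ))
  albumin <- band_sum(list(
    c(3300, 120, 0.055),
    c(2955,  45, 0.014),
    c(1656,  24, 0.100),   # amide I, alpha-helix
    c(1546,  22, 0.050),
    c(1400,  28, 0.022),
    c(1310,  30, 0.008)
  ))
  mat <- band_sum(list(
    c(3350, 150, 0.015),
    c(1595,  40, 0.012),
    c(1450,  50, 0.020),
    c(1100,  70, 0.030)
  ))
  list(IgG = igg, albumin = albumin, matrix = mat)
}

#' Simulation configuration for synthetic replicate ATR spectra
#'
#' Collects and validates every knob of the synthetic study design. Defaults
#' emulate the design the pipeline targets: 250 serum samples measured in
#' replicates of five, IgG spanning roughly 5-3000 mg/dL with about half the
#' samples below the 1000 mg/dL FTPI cut-off.
#'
#' @param n_samples Number of serum samples.
#' @param replicates_per_sample Replicate spectra per sample (>= 2).
#' @param igg_range Closed `(low, high)` IgG truth range in mg/dL.
#' @param noise_sd Detector noise SD in absorbance units per point.
#' @param scatter_sd SD of the lognormal film-thickness factor (unitless
#'   multiplicative spread across replicates).
#' @param baseline_drift_sd SD of the additive baseline offset/tilt (AU).
#' @param diamond_noise_sd Extra noise SD applied only inside the
#'   2200-1900 cm^-1 window (diamond coating absorptions).
#' @param outlier_rate Per-replicate probability of a gross anomaly: an
#'   additive offset of `10 * noise_sd` plus a 20% multiplicative scale
#'   error applied to the whole spectrum.
#' @param seed Integer seed; all randomness in [simulate_dataset()] flows
#'   from it.
#' @param spacing Wavenumber grid spacing, cm^-1 per point.
#' @param albumin_mean,albumin_sd Serum albumin concentration distribution
#'   (g/dL), truncated at 0.5 g/dL.
#' @param matrix_mean,matrix_sd Non-protein residue distribution (g/dL),
#'   truncated at 0.5 g/dL.
#' @param pre_colostrum_fraction Fraction of samples from calves bled before
#'   colostrum ingestion (low IgG, assayed with the ultra-low-range kit).
#' @param cow_fraction Fraction of samples from adult cows.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 250,
                       replicates_per_sample = 5,
                       igg_range = c(5, 3000),
                       noise_sd = 0.001,
                       scatter_sd = 0.1,
                       baseline_drift_sd = 0.001,
                       diamond_noise_sd = 0.003,
                       outlier_rate = 0.01,
                       seed = 1,
                       spacing = 4,
                       albumin_mean = 3.0, albumin_sd = 0.3,
                       matrix_mean = 2.0, matrix_sd = 0.3,
                       pre_colostrum_fraction = 0.032,
                       cow_fraction = 0.168) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    replicates_per_sample = as.integer(replicates_per_sample),
    igg_range = as.numeric(igg_range),
    noise_sd = noise_sd, scatter_sd = scatter_sd,
    baseline_drift_sd = baseline_drift_sd,
    diamond_noise_sd = diamond_noise_sd,
    outlier_rate = outlier_rate,
    seed = as.integer(seed), spacing = spacing,
    albumin_mean = albumin_mean, albumin_sd = albumin_sd,
    matrix_mean = matrix_mean, matrix_sd = matrix_sd,
    pre_colostrum_fraction = pre_colostrum_fraction,
    cow_fraction = cow_fraction
  )
  if (cfg$n_samples < 1L) stop("`n_samples` must be >= 1")
  if (cfg$replicates_per_sample < 2L) {
    stop("`replicates_per_sample` must be >= 2")
  }
  if (length(cfg$igg_range) != 2L || !all(is.finite(cfg$igg_range)) ||
      cfg$igg_range[1] >= cfg$igg_range[2] || cfg$igg_range[1] < 0) {
    stop("`igg_range` must be a finite (low, high) pair with 0 <= low < high")
  }
  sds <- c(cfg$noise_sd, cfg$scatter_sd, cfg$baseline_drift_sd,
           cfg$diamond_noise_sd, cfg$albumin_sd, cfg$matrix_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all standard deviations must be finite and >= 0")
  }
  if (!is.finite(cfg$outlier_rate) || cfg$outlier_rate < 0 ||
      cfg$outlier_rate > 1) {
    stop("`outlier_rate` must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Draw reference IgG concentrations
#'
#' Samples IgG truth values (mg/dL) from a truncated lognormal distribution
#' (meanlog `log(1250)`, sdlog 1, truncated to `range` by inverse-CDF
#' sampling). At the default range this is right-skewed with roughly half
#' the mass below the 1000 mg/dL FTPI cut-off, mirroring the prevalence a
#' calf/cow serum bank presents.
#'
#' @param n Number of values to draw.
#' @param range Closed `(low, high)` truncation range, mg/dL, `low < high`.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so the function can run inside a larger seeded simulation).
#' @param meanlog,sdlog Lognormal parameters before truncation.
#' @return Numeric vector of `n` IgG concentrations inside `range`.
#' @export
draw_igg_truth <- function(n, range = c(5, 3000), seed = NULL,
                           meanlog = log(1250), sdlog = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be >= 1")
  range <- as.numeric(range)
  if (length(range) != 2L || !all(is.finite(range)) || range[1] >= range[2]) {
    stop("`range` must be a finite (low, high) pair with low < high")
  }
  draw <- function() {
    p <- stats::plnorm(range, meanlog = meanlog, sdlog = sdlog)
    u <- stats::runif(n, p[1], p[2])
    stats::qlnorm(u, meanlog = meanlog, sdlog = sdlog)
  }
  x <- if (is.null(seed)) draw() else with_seed(seed, draw())
  pmin(pmax(x, range[1]), range[2])
}

# Noise-free Beer-Lambert mixture: concentrations in g/dL, thickness
# dimensionless. Exposed internally so linearity is testable in isolation.
mixture_spectrum <- function(components, conc, thickness = 1) {
  stopifnot(length(conc) == length(components))
  thickness * Reduce(`+`, Map(`*`, components, conc))
}

#' Apply the generator's gross-outlier anomaly to one replicate
#'
#' The whole-spectrum anomaly used for injected outlier replicates: a 20%
#' multiplicative scale error plus an additive offset of `10 * noise_sd`.
#' Exposed so the outlier screen can be exercised on controlled fixtures.
#' Note the anomaly is affine, so it is exactly invisible after SNV
#' normalization (which removes offset and scale per spectrum); screens
#' intended to catch it must run on non-normalized spectra. Dixon's r10
#' statistic flags at most one replicate per point, so two identical
#' anomalies in one replicate group mask each other -- the screen is a
#' single-outlier test, as is standard for n <= 7.
#'
#' @param spectrum Numeric absorbance vector.
#' @param noise_sd The generator's detector-noise SD (AU).
#' @return The anomalous spectrum `1.2 * spectrum + 10 * noise_sd`.
#' @export
inject_gross_outlier <- function(spectrum, noise_sd) {
  1.2 * spectrum + 10 * noise_sd
}

#' Simulate a replicate ATR dataset of dried serum films
#'
#' Generates `n_samples` serum samples, each measured as
#' `replicates_per_sample` replicate spectra on one shared wavenumber grid,
#' following the Beer-Lambert mixture model described in
#' [build_component_library()]. Per replicate the film-thickness factor is
#' `exp(N(0, scatter_sd))`, white noise of SD `noise_sd` is added
#' everywhere, extra noise of SD `diamond_noise_sd` only inside
#' 2200-1900 cm^-1, and a linear baseline with offset and tilt of SD
#' `baseline_drift_sd` is superimposed. With probability `outlier_rate` a
#' replicate is made a gross outlier (whole-spectrum offset of
#' `10 * noise_sd` plus a 20% scale error) and flagged in the truth table.
#'
#' Samples are assigned an animal class (`calf`, `cow`, `pre_colostrum`);
#' pre-colostrum calves get low IgG truth (5-120 mg/dL) and the `ultra_low`
#' RID kit tag, everyone else the `standard` kit tag.
#'
#' @param config A [sim_config()].
#' @return A list of class `atr_dataset` with elements
#'   \describe{
#'     \item{grid}{shared descending wavenumber grid}
#'     \item{samples}{data frame: `sample_id`, `animal_class`,
#'       `igg_reference` (mg/dL), `kit`}
#'     \item{spectra}{numeric matrix, one row per replicate spectrum}
#'     \item{replicates}{data frame aligned with `spectra` rows:
#'       `sample_id`, `replicate_id`, `outlier_truth`}
#'   }
#' @examples
#' ds <- simulate_dataset(sim_config(n_samples = 4, seed = 7))
#' dim(ds$spectra)   # 20 replicate spectra
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  grid <- make_default_grid(config$spacing)
  wn <- as.numeric(grid)
  comps <- build_component_library(grid)
  p <- length(wn)
  n <- config$n_samples
  reps <- config$replicates_per_sample
  diamond <- wn <= 2200 & wn >= 1900
  mid <- (wn[1] + wn[p]) / 2
  span <- wn[1] - wn[p]

  with_seed(config$seed, {
    n_pre <- round(config$pre_colostrum_fraction * n)
    n_cow <- round(config$cow_fraction * n)
    n_cow <- min(n_cow, n - n_pre)
    cls <- rep("calf", n)
    if (n_pre > 0) cls[seq_len(n_pre)] <- "pre_colostrum"
    if (n_cow > 0) cls[n_pre + seq_len(n_cow)] <- "cow"
    cls <- sample(cls)

    igg <- draw_igg_truth(n, config$igg_range)
    pre <- cls == "pre_colostrum"
    if (any(pre)) {
      lo <- max(config$igg_range[1], 5)
      hi <- min(config$igg_range[2], 120)
      igg[pre] <- stats::runif(sum(pre), lo, hi)
    }
    albumin <- pmax(0.5, stats::rnorm(n, config$albumin_mean, config$albumin_sd))
    other <- pmax(0.5, stats::rnorm(n, config$matrix_mean, config$matrix_sd))

    spectra <- matrix(0, n * reps, p)
    outlier_truth <- logical(n * reps)
    row <- 0L
    for (i in seq_len(n)) {
      conc <- c(IgG = igg[i] / 1000, albumin = albumin[i], matrix = other[i])
      clean <- mixture_spectrum(comps, conc)
      for (r in seq_len(reps)) {
        row <- row + 1L
        thick <- exp(stats::rnorm(1, 0, config$scatter_sd))
        b0 <- stats::rnorm(1, 0, config$baseline_drift_sd)
        b1 <- stats::rnorm(1, 0, config$baseline_drift_sd)
        s <- thick * clean + b0 + b1 * (wn - mid) / span +
          stats::rnorm(p, 0, config$noise_sd)
        if (any(diamond) && config$diamond_noise_sd > 0) {
          s[diamond] <- s[diamond] +
            stats::rnorm(sum(diamond), 0, config$diamond_noise_sd)
        }
        is_out <- stats::runif(1) < config$outlier_rate
        if (is_out) s <- inject_gross_outlier(s, config$noise_sd)
        spectra[row, ] <- s
        outlier_truth[row] <- is_out
      }
    }

    ids <- sprintf("S%04d", seq_len(n))
    samples <- data.frame(
      sample_id = ids, animal_class = cls, igg_reference = igg,
      kit = ifelse(pre, "ultra_low", "standard"),
      stringsAsFactors = FALSE
    )
    replicates <- data.frame(
      sample_id = rep(ids, each = reps),
      replicate_id = rep(seq_len(reps), n),
      outlier_truth = outlier_truth,
      stringsAsFactors = FALSE
    )
    rownames(spectra) <- paste0(replicates$sample_id, "_r",
                                replicates$replicate_id)
    structure(list(grid = grid, samples = samples, spectra = spectra,
                   replicates = replicates, config = config),
              class = "atr_dataset")
  })
}

#' @export
print.atr_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic ATR dataset: %d samples x %d replicates (%d spectra), ",
    "%d grid points\nIgG truth: %.1f-%.1f mg/dL; %d replicate(s) injected ",
    "as gross outliers\n"),
    nrow(x$samples), x$config$replicates_per_sample, nrow(x$spectra),
    length(as.numeric(x$grid)), min(x$samples$igg_reference),
    max(x$samples$igg_reference), sum(x$replicates$outlier_truth)))
  invisible(x)
}
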