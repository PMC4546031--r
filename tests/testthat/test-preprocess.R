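test_that("Savitzky-Golay smoothing matches a brute-force local fit and
           reproduces low-degree polynomials", {
  expect_equal(savgol_smooth(rep(3.5, 30)), rep(3.5, 30))

  x <- seq(0, 5, length.out = 41)
  y <- 3 * x^2 - x + 2
  sm <- savgol_smooth(y, window = 9, polyorder = 2)
  interior <- 5:37
  expect_equal(sm[interior], y[interior], tolerance = 1e-10)

  set.seed(42)
  r <- rnorm(60)
  expect_equal(savgol_smooth(r, 9, 2), sg_oracle(r, 9, 2), tolerance = 1e-10)
  expect_equal(savgol_smooth(r, 11, 3), sg_oracle(r, 11, 3), tolerance = 1e-10)

  expect_error(savgol_smooth(r, window = 8), "odd")
  expect_error(savgol_smooth(rnorm(5), window = 9), "length")
})

test_that("interior smoothing agrees with the signal package's filter", {
  skip_if_not_installed("signal")
  set.seed(7)
  x <- cumsum(rnorm(80))
  ours <- savgol_smooth(x, 9, 2)
  theirs <- signal::sgolayfilt(x, p = 2, n = 9)
  expect_equal(ours[5:76], theirs[5:76], tolerance = 1e-10)
})

test_that("SG derivatives follow the increasing-wavenumber convention", {
  grid <- make_default_grid(8)
  wn <- as.numeric(grid)[1:400]       # uniform part of the grid
  a <- 0.003
  d1 <- savgol_derivative(a * wn, order = 1, spacing = 8)
  interior <- 5:396
  expect_equal(d1[interior], rep(a, length(interior)), tolerance = 1e-8)

  d2 <- savgol_derivative(a * wn^2, order = 2, spacing = 8)
  expect_equal(d2[interior], rep(2 * a, length(interior)), tolerance = 1e-6)

  expect_equal(savgol_derivative(rep(1, 30), order = 1), rep(0, 30),
               tolerance = 1e-12)
  set.seed(1)
  r <- rnorm(50)
  expect_equal(savgol_derivative(r, 1, spacing = 2),
               sg_oracle(r, 9, 2, deriv = 1, spacing = 2), tolerance = 1e-10)
  expect_error(savgol_derivative(r, order = 3), "1 or 2")
})

test_that("SNV centres to mean 0 and sample SD 1; vector norm to unit length", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  z <- snv(runif(50))
  expect_equal(snv(z), z, tolerance = 1e-12)        # idempotent
  expect_error(snv(rep(2, 10)), "constant")
  expect_error(snv(3), "2 points")

  expect_equal(vector_normalize(c(3, 4)), c(0.6, 0.8))
  expect_equal(vector_normalize(c(-3, 4)), c(-0.6, 0.8))
  v <- vector_normalize(rnorm(20))
  expect_equal(vector_normalize(v), v, tolerance = 1e-12)
  expect_error(vector_normalize(c(0, 0)), "zero")

  set.seed(8)
  for (i in 1:25) {
    x <- rnorm(sample(10:200, 1))
    expect_equal(mean(snv(x)), 0, tolerance = 1e-12)
    expect_equal(sd(snv(x)), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(vector_normalize(x)^2)), 1, tolerance = 1e-12)
  }
})

test_that("region selection keeps exactly the points inside the closed windows", {
  grid <- make_default_grid(4)
  wn <- as.numeric(grid)
  vals <- seq_along(wn)

  full <- select_regions(grid, vals, regions = list(c(4000, 650)))
  expect_equal(full$values, vals)

  sel <- select_regions(grid, vals)
  # enumeration oracle over the default windows
  expected <- sum(wn <= 3700 & wn >= 2600) + sum(wn <= 1800 & wn >= 1300)
  expect_length(sel$idx, expected)
  expect_true(all(sel$grid <= 3700 & sel$grid >= 1300))
  expect_true(all(diff(sel$grid) < 0))      # descending, high region first

  m <- rbind(vals, vals * 2)
  selm <- select_regions(grid, m)
  expect_equal(dim(selm$values), c(2L, expected))

  expect_error(select_regions(grid, vals, regions = list(c(5000, 4500))),
               "no grid point")
})

test_that("Dixon Q statistics and critical values behave per the r10 rule", {
  q <- dixon_q(c(1, 2, 3, 4, 10))
  expect_equal(q$q_high, 6 / 9, tolerance = 1e-12)
  expect_equal(q$critical, 0.710)
  expect_true(is.na(q$outlier))             # 0.667 < 0.710

  q <- dixon_q(c(1, 2, 3, 4, 100))
  expect_equal(q$q_high, 96 / 99, tolerance = 1e-12)
  expect_equal(q$outlier, 5L)

  q <- dixon_q(c(-50, 2, 3, 4, 5))          # low-end outlier
  expect_equal(q$outlier, 1L)

  q <- dixon_q(rep(5, 5))
  expect_true(is.na(q$q_low) && is.na(q$outlier))

  expect_error(dixon_q(c(1, 2)), "n = 3..7")
  expect_error(dixon_q(1:8), "n = 3..7")
  expect_error(dixon_q(1:5, confidence = 0.8), "confidence")
  expect_equal(dixon_q(c(1, 2, 3), confidence = 0.99)$critical, 0.994)
})

test_that("whole-replicate screen excludes gross offsets but not partial anomalies", {
  set.seed(11)
  p <- 40
  clean <- matrix(rnorm(5 * p, sd = 0.001), 5, p)
  clean[5, ] <- clean[5, ] + 0.1            # gross whole-spectrum offset
  rep5 <- flag_outlier_replicates(clean)
  expect_gt(rep5$flagged_fraction[5], 0.5)
  expect_true(rep5$excluded[5])
  expect_false(any(rep5$excluded[1:4]))

  # identical replicates: nothing to flag
  same <- matrix(1, 5, p)
  rep0 <- flag_outlier_replicates(same)
  expect_equal(rep0$flagged_fraction, rep(0, 5))
  expect_false(any(rep0$excluded))

  # anomalous at exactly 40% of points: flagged fraction 0.4, retained
  base <- matrix(rnorm(5 * 10, sd = 0.001), 5, 10)
  base[3, 1:4] <- base[3, 1:4] + 1
  rep40 <- flag_outlier_replicates(base)
  expect_equal(rep40$flagged_fraction[3], 0.4)
  expect_false(rep40$excluded[3])

  expect_error(flag_outlier_replicates(clean[1:2, ]), "at least 3")
})

test_that("screen stays quiet on exchangeable white noise", {
  set.seed(5)
  frac <- c()
  excl <- 0
  for (i in 1:100) {
    R <- matrix(rnorm(5 * 120), 5, 120)
    rep <- flag_outlier_replicates(R)
    excl <- excl + sum(rep$excluded)
    frac <- c(frac, rep$flagged_fraction)
  }
  expect_equal(excl, 0)
  expect_lt(mean(frac), 0.05)   # ~5% of points trigger at 95% confidence,
                                # split across the 5 replicates
})

test_that("replicate averaging uses survivors only", {
  m <- rbind(c(0, 0, 0), c(2, 2, 2))
  expect_equal(average_replicates(m), c(1, 1, 1))

  set.seed(3)
  m5 <- matrix(rnorm(5 * 6), 5, 6)
  m5[2, ] <- m5[2, ] + 50
  rep <- flag_outlier_replicates(m5)
  expect_true(rep$excluded[2])
  expect_equal(average_replicates(m5, rep), colMeans(m5[-2, ]))

  same <- matrix(7, 4, 3)
  expect_equal(average_replicates(same), rep(7, 3))
  expect_error(average_replicates(m5[1, , drop = FALSE]), "2 replicates")
})

test_that("the pipeline composes its stages in the documented order", {
  ds <- small_dataset(n = 1, seed = 21, spacing = 16, noise_sd = 5e-4,
                      outlier_rate = 0)
  reps <- ds$spectra
  grid <- ds$grid

  # identity spec on identical replicates returns the replicate
  one <- matrix(rep(reps[1, ], 5), 5, ncol(reps), byrow = TRUE)
  idspec <- preprocess_spec(smoothing = "none", normalization = "none",
                            regions = list(c(4000, 650)))
  out <- apply_pipeline(one, grid, idspec)
  expect_equal(out$spectrum, reps[1, ], tolerance = 1e-12)

  # SNV contract holds per replicate before averaging
  snvspec <- preprocess_spec(smoothing = "savgol", normalization = "snv",
                             regions = list(c(4000, 650)))
  out <- apply_pipeline(reps, grid, snvspec)
  # replicates were normalized on the full range, then regions selected:
  # full-range rows have mean 0 / sd 1
  full <- t(apply(reps, 1, function(r) snv(savgol_smooth(r))))
  expect_equal(unname(rowMeans(full)), rep(0, 5), tolerance = 1e-12)

  # stage-by-stage manual application equals apply_pipeline
  spec <- pp_preset("smooth+snv")
  manual <- t(apply(reps, 1, function(r) snv(savgol_smooth(r, 9, 2))))
  sel <- select_regions(grid, manual, spec$regions)
  rep_manual <- flag_outlier_replicates(sel$values, 0.95, 0.5)
  avg_manual <- average_replicates(sel$values, rep_manual)
  auto <- apply_pipeline(reps, grid, spec)
  expect_equal(auto$spectrum, avg_manual, tolerance = 1e-12)
  expect_equal(auto$report$flagged_fraction, rep_manual$flagged_fraction)

  # derivative presets run end to end and change the representation
  d1 <- apply_pipeline(reps, grid, pp_preset("d1+snv"))
  expect_equal(length(d1$spectrum), length(auto$spectrum))
  expect_false(isTRUE(all.equal(d1$spectrum, auto$spectrum)))
})

test_that("preprocess_spec validates its fields", {
  expect_error(preprocess_spec(window = 8), "odd")
  expect_error(preprocess_spec(window = 3, polyorder = 2), "odd|polyorder")
  expect_error(preprocess_spec(regions = list(c(3700, 2600), c(2700, 1300))),
               "overlap")
  expect_error(preprocess_spec(outlier_confidence = 0.5), "confidence")
  expect_error(preprocess_spec(outlier_point_fraction = 0), "0, 1")
  expect_equal(pp_preset("d2")$derivative, "second")
  expect_length(pp_presets(), 9)
})
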