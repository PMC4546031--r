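test_that("rmse and pearson follow their definitions", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(5, 5 + 2.5), 2.5)
  expect_error(rmse(1:3, 1:4), "equal-length")
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")

  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson(x, 2 * x + 5), 1)
  expect_equal(pearson(x, -x), -1)
  y <- c(2, 1, 5, 4, 8)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), hand, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
})

test_that("Lin's CCC penalizes location shift exactly as the closed form says", {
  x <- c(10, 20, 30, 40, 55)
  expect_equal(concordance_ccc(x, x), 1)

  s2 <- mean((x - mean(x))^2)
  for (c0 in c(5, -12, 40)) {
    expect_equal(concordance_ccc(x, x + c0), 2 * s2 / (2 * s2 + c0^2),
                 tolerance = 1e-10)
  }

  # independent noise has concordance near zero
  set.seed(14)
  a <- rnorm(5000); b <- rnorm(5000)
  expect_lt(abs(concordance_ccc(a, b)), 0.1)

  # |CCC| <= |r| always; equality when means and variances match
  set.seed(15)
  for (i in 1:20) {
    u <- rnorm(30); v <- 2 * u + rnorm(30)
    expect_lte(abs(concordance_ccc(u, v)), abs(pearson(u, v)) + 1e-12)
  }
  u <- rnorm(100); v <- rev(u)    # same mean and variance
  expect_equal(concordance_ccc(u, v), pearson(u, v), tolerance = 1e-12)

  expect_error(concordance_ccc(rep(1, 4), rep(1, 4)), "undefined")
})

test_that("Bland-Altman limits use test-minus-reference and 1.96 sample SDs", {
  ba <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ba$mean_diff, ba$loa_low, ba$loa_high), c(0, 0, 0))

  ba <- bland_altman(c(10, 20), c(17, 27))    # constant offset, zero spread
  expect_equal(c(ba$mean_diff, ba$loa_low, ba$loa_high), c(7, 7, 7))

  ba <- bland_altman(c(0, 0), c(-1, 1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)

  # ~95% of normal differences fall inside the limits
  set.seed(9)
  d <- rnorm(1000)
  ba <- bland_altman(rep(0, 1000), d)
  expect_gte(mean(d >= ba$loa_low & d <= ba$loa_high), 0.93)
})

test_that("CV* applies the small-sample correction 1 + 1/(4n)", {
  r <- cv_star(c(90, 95, 100, 105, 110))
  expect_equal(r$cv, sd(c(90, 95, 100, 105, 110)) / 100, tolerance = 1e-12)
  expect_equal(r$cv_star, r$cv * 1.05, tolerance = 1e-12)   # n = 5
  expect_equal(cv_star(c(7, 7, 7))$cv_star, 0)
  expect_error(cv_star(c(-1, 1)), "zero mean")
  expect_error(cv_star(5), "2 replicates")
})

test_that("RPD/RER ratios and interpretation bands", {
  r <- rpd_rer(876, 2977, 876)
  expect_equal(r$rpd, 1)
  expect_equal(r$interpretation, "poor")
  expect_equal(rpd_rer(876, 2977, 400)$interpretation, "screening")
  expect_equal(rpd_rer(876, 2977, 326)$interpretation, "quantification")
  expect_equal(rpd_rer(900, 2977, 250)$interpretation,
               "accurate quantification")
  expect_error(rpd_rer(0, 10, 1), "> 0")
  expect_error(rpd_rer(10, 10, -1), "> 0")
})

test_that("FTPI classification is strictly below the cut-off", {
  expect_true(classify_ftpi(999.9))
  expect_false(classify_ftpi(1000))
  expect_true(classify_ftpi(0))
  expect_error(classify_ftpi(-5), ">= 0")
})

test_that("diagnostic table counts, rates and degenerate denominators", {
  ref <- c(500, 800, 1200, 2000)
  pred <- c(400, 1100, 1300, 1900)
  dt <- diagnostic_table(ref, pred)
  expect_equal(c(dt$tp, dt$fp, dt$tn, dt$fn), c(1, 0, 2, 1))
  expect_equal(dt$tp + dt$fp + dt$tn + dt$fn, dt$n)
  expect_equal(dt$sensitivity, 0.5)
  expect_equal(dt$specificity, 1)
  expect_equal(dt$accuracy, 0.75)

  # no condition-positives: sensitivity undefined, specificity defined
  dt <- diagnostic_table(c(1500, 2000), c(1400, 900))
  expect_true(is.na(dt$sensitivity))
  expect_equal(dt$specificity, 0.5)

  # cut-off 0 makes everything test-negative
  dt <- diagnostic_table(ref, pred, cutoff = 0)
  expect_equal(dt$tp + dt$fp, 0)
  expect_true(is.na(dt$sensitivity))
  expect_equal(dt$specificity, 1)

  # brute-force recount on simulated values
  set.seed(20)
  r <- runif(200, 0, 3000); p <- r + rnorm(200, 0, 300)
  dt <- diagnostic_table(r, p)
  expect_equal(dt$tp, sum(r < 1000 & pmax(p, 0) < 1000))
  expect_equal(dt$true_prevalence, mean(r < 1000))
  expect_equal(dt$apparent_prevalence, mean(pmax(p, 0) < 1000))
})

test_that("evaluate_agreement bundles the metrics coherently", {
  set.seed(30)
  ref <- runif(80, 100, 2900)
  pred <- ref + rnorm(80, -20, 150)
  rep <- evaluate_agreement(ref, pred)
  expect_equal(rep$rmse, rmse(ref, pred))
  expect_equal(rep$pearson_r, pearson(ref, pred))
  expect_lte(abs(rep$ccc), abs(rep$pearson_r) + 1e-12)
  expect_equal(rep$sd_reference, sqrt(mean((ref - mean(ref))^2)))
  expect_equal(rep$rpd, rep$sd_reference / rep$rmse)
  expect_equal(rep$rer, (max(ref) - min(ref)) / rep$rmse)
  expect_lte(rep$bland_altman$loa_low, rep$bland_altman$mean_diff)
  expect_gte(rep$bland_altman$loa_high, rep$bland_altman$mean_diff)
})
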