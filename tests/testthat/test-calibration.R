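# independent closed-form least-squares oracle
ols_line <- function(x, y) {
  m <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = m, intercept = mean(y) - m * mean(x))
}

test_that("exact lines are fitted exactly", {
  x <- 0:4
  d <- data.frame(quantity_fg = 10 * 10^x, tc_ratio = 0.2 * x + 0.01)
  fit <- fit_calibration(d)
  expect_equal(fit$slope, 0.2)
  expect_equal(fit$intercept, 0.01)
  expect_equal(fit$sigma, 0)
  expect_equal(fit$r_squared, 1)

  d2 <- data.frame(quantity_fg = c(10, 1e5), tc_ratio = c(0, 0.8))
  fit2 <- fit_calibration(d2)
  expect_equal(fit2$slope, 0.2)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)
})

test_that("single-quantity data is rank deficient", {
  d <- data.frame(quantity_fg = rep(100, 5), tc_ratio = runif(5))
  expect_error(fit_calibration(d), "rank deficiency")
})

test_that("the fixture tables reproduce the recomputed calibration", {
  fx <- load_fixture_readings()
  fit <- fit_calibration(fx)
  oracle <- ols_line(log10(fx$quantity_fg / 10), fx$tc_ratio)
  expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-12)
  # per-decade slope ~0.20, intercept ~0.015 (3-decimal tables cannot
  # regenerate the published 0.203 / 0.0118 exactly)
  expect_equal(fit$slope, 0.20016, tolerance = 1e-4)
  expect_equal(fit$intercept, 0.014573, tolerance = 1e-3)
  expect_equal(fit$r_squared, 0.9784, tolerance = 1e-3)
})

test_that("r_squared follows the SS decomposition and stays in [0, 1]", {
  expect_equal(r_squared(list(ss_residual = 0, ss_total = 3)), 1)
  # predicting the mean leaves SS_res = SS_tot
  y <- c(1, 2, 3, 6)
  ss <- sum((y - mean(y))^2)
  expect_equal(r_squared(list(ss_residual = ss, ss_total = ss)), 0)
  expect_error(r_squared(list(ss_residual = 0, ss_total = 0)), "degenerate")
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    f <- fit_calibration(data.frame(quantity_fg = 10 * 10^x, tc_ratio = pmax(y - min(y), 0)))
    expect_gte(f$r_squared, 0); expect_lte(f$r_squared, 1)
  }
})

test_that("std_error is the N-divisor RMS of residuals", {
  expect_equal(std_error(c(0, 0, 0)), 0)
  expect_equal(std_error(2, 1), 2)
  expect_equal(std_error(c(3, 4), 2), sqrt(25 / 2))
  expect_equal(std_error(c(3, 4)), 3.5355, tolerance = 1e-4)
  expect_error(std_error(numeric(0)), "at least one")
})

test_that("LOD and LOQ follow the slope-normalised formulas", {
  expect_equal(lod(0, 0.007, 0.203), 1.645 * 0.007 / 0.203)
  expect_equal(round(lod(0, 0.007, 0.203), 5), 0.05672)
  expect_equal(round(loq(0.007, 0.203), 5), 0.34483)
  expect_equal(lod(0.1, 0, 2), 0.1)
  expect_equal(loq(0, 2), 0)
  expect_error(lod(0, 0.1, 0), "slope")
  expect_error(loq(0.1, 0), "slope")
})

test_that("class statistics use the n-1 standard deviation and percent CV", {
  fx <- load_fixture_readings()
  st <- class_stats(fx)
  expect_equal(st$n, rep(15, 5))
  for (q in names(published_class_sd)) {
    expect_equal(round(st$sd[st$quantity_fg == as.numeric(q)], 6),
                 unname(published_class_sd[q]), info = q)
  }
  expect_true(is.na(st$cv[st$quantity_fg == 10]))   # zero mean: CV undefined

  same <- data.frame(quantity_fg = rep(100, 4), tc_ratio = rep(0.5, 4))
  st2 <- class_stats(same)
  expect_equal(st2$sd, 0); expect_equal(st2$cv, 0)

  single <- data.frame(quantity_fg = c(100, 100, 200),
                       tc_ratio = c(0.1, 0.2, 0.3))
  expect_error(class_stats(single), "single reading")
})

test_that("predict_quantity inverts the calibration line", {
  pm <- published_model()
  expect_equal(predict_quantity(pm$intercept, pm), 10)
  expect_equal(predict_quantity(0.8238, pm), 1e5, tolerance = 1e-9)
  expect_equal(predict_quantity(0.203 * 2 + 0.0118, pm), 1e3,
               tolerance = 1e-9)
  # round trip through the fitted line is exact in x
  fit <- fit_calibration(data.frame(quantity_fg = 10 * 10^(0:4),
                                    tc_ratio = 0.25 * 0:4 + 0.02))
  for (x in c(0, 1.5, 4)) {
    expect_equal(predict_quantity(fit$slope * x + fit$intercept, fit),
                 10 * 10^x, tolerance = 1e-9)
  }
})

test_that("mass, concentration and molarity conversions agree", {
  expect_equal(mass_from_concentration(10000, 10), 1e5)  # 10 ng/mL, 10 uL -> 100 pg
  expect_equal(mass_from_concentration(1, 10), 10)       # 1 pg/mL, 10 uL -> 10 fg
  expect_equal(concentration_from_mass(0, 10), 0)
  expect_equal(concentration_from_mass(mass_from_concentration(37, 10), 10), 37)
  expect_error(mass_from_concentration(1, 0), "> 0")
  # 66.5 kDa albumin: 1.71 pg/mL is ~0.000026 nM
  expect_equal(concentration_to_nM(1.71, 66500), 2.57e-5, tolerance = 1e-2)
})

test_that("fitted parameters recover the generating line", {
  m0 <- 0.2; b0 <- 0.01
  x <- rep(0:4, each = 15)
  # vanishing noise: coefficients converge to the truth
  set.seed(77)
  y <- m0 * x + b0 + rnorm(length(x), sd = 1e-9)
  f0 <- fit_calibration(data.frame(quantity_fg = 10 * 10^x, tc_ratio = y))
  expect_equal(f0$slope, m0, tolerance = 1e-6)
  expect_equal(f0$intercept, b0, tolerance = 1e-6)
  # realistic noise: within three standard errors
  s <- 0.02
  se_slope <- s / sqrt(sum((x - mean(x))^2))
  se_int <- s * sqrt(1 / length(x) + mean(x)^2 / sum((x - mean(x))^2))
  set.seed(78)
  y <- m0 * x + b0 + rnorm(length(x), sd = s)
  y <- pmax(y, 0)
  f <- fit_calibration(data.frame(quantity_fg = 10 * 10^x, tc_ratio = y))
  expect_lt(abs(f$slope - m0), 3 * se_slope)
  expect_lt(abs(f$intercept - b0), 3 * se_int)
})

test_that("blank readings raise the limit of blank", {
  fx <- load_fixture_readings()
  blanks <- c(0.01, 0.012, 0.008)
  fit <- fit_calibration(fx, blanks = blanks)
  expect_equal(fit$lob, mean(blanks) + 1.645 * sd(blanks))
  expect_equal(fit$lod, fit$lob + 1.645 * fit$sigma / fit$slope)
})
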