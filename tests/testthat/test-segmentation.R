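# independent oracle: direct intra-class variance minimization over bin cuts
brute_force_otsu <- function(values, bins = 256L) {
  lo <- min(values); hi <- max(values)
  idx <- pmin(floor((values - lo) / (hi - lo) * bins) + 1L, bins)
  mids <- lo + (idx - 0.5) * (hi - lo) / bins
  ssq <- function(v) if (length(v) == 0) NA else sum((v - mean(v))^2)
  intra <- sapply(seq_len(bins - 1L), function(cut) {
    ssq(mids[idx <= cut]) + ssq(mids[idx > cut])
  })
  cut <- which.min(intra)   # NA (empty class) never minimal; first tie wins
  lo + cut * (hi - lo) / bins
}

test_that("ratio image divides red by green and flags zero green invalid", {
  img <- solid_image(4, 4, 160, 130, 130)
  r <- ratio_image(img)
  expect_equal(r$ratio[1, 1], 160 / 130, tolerance = 1e-12)
  expect_equal(round(r$ratio[1, 1], 4), 1.2308)

  img2 <- solid_image(2, 2, 70, 70, 10)
  expect_true(all(ratio_image(img2)$ratio == 1))

  g0 <- solid_image(2, 2, 50, 0, 10)
  r0 <- ratio_image(g0)
  expect_true(all(!r0$valid))
  expect_true(all(is.na(r0$ratio)))
})

test_that("otsu_threshold separates well-defined groups", {
  th <- otsu_threshold(c(rep(1, 50), rep(2, 50)))
  expect_gte(th, 1); expect_lt(th, 2)

  th2 <- otsu_threshold(c(1, 1, 1, 1, 10))
  expect_gt(th2, 1); expect_lt(th2, 10)
  expect_equal(sum(c(1, 1, 1, 1, 10) > th2), 1)

  expect_error(otsu_threshold(rep(3, 10)), "degenerate")
  expect_error(otsu_threshold(c(1, 2), levels = 1), "levels >= 2")
})

test_that("otsu_threshold matches brute-force intra-class minimization", {
  set.seed(101)
  for (i in 1:25) {
    v <- c(rnorm(sample(10:60, 1), 1, 0.05),
           rnorm(sample(10:60, 1), runif(1, 1.3, 3), 0.2))
    expect_equal(otsu_threshold(v), brute_force_otsu(v), tolerance = 1e-12)
  }
})

test_that("multilevel thresholds are ascending and split three groups", {
  v <- c(rep(0, 30), rep(5, 30), rep(10, 30))
  th <- otsu_threshold(v, levels = 3)
  expect_length(th, 2)
  expect_true(th[1] < th[2])
  expect_equal(as.integer(table(cut(v, c(-Inf, th, Inf)))), c(30, 30, 30))
})

test_that("masking uses a strict inequality at the threshold", {
  # 9x9 image: center box is [3,6)x[3,6); control row y=3, test row y=4.
  # Control ratios {0, 128, 128} span [0, 128]; ties resolve to the smallest
  # cut, whose bin edge is 128/256 = 0.5 exactly. Test ratios
  # {0.5, 0.75, 0.25} -> only 0.75 enters the mask.
  red <- matrix(0L, 9, 9); green <- matrix(1L, 9, 9)
  red[4, 4:6] <- c(0L, 128L, 128L)
  red[5, 4:6] <- c(64L, 96L, 32L); green[5, 4:6] <- 128L
  img <- rgb_image(red, green, matrix(0L, 9, 9))
  r <- ratio_image(img)
  rp <- line_regions(center_box(9, 9))
  mask <- build_mask(r, rp$control, list(rp$control, rp$test))
  expect_equal(mask$threshold, 0.5)
  expect_equal(mask$values[5, 4:6], c(0L, 1L, 0L))  # 0.5 is NOT above TH
  expect_equal(mask$values[4, 4:6], c(0L, 1L, 1L))  # control 128s are above
})

test_that("uniform thresholding region is a degenerate input", {
  img <- solid_image(9, 9, 100, 100, 100)
  r <- ratio_image(img)
  rp <- line_regions(center_box(9, 9))
  expect_error(build_mask(r, rp$control, rp$test), "degenerate")
})

test_that("mask equals painted band pixels on a noiseless strip", {
  for (prof in c("coverage", "flat")) {
    sp <- synthetic_strip_spec(test_strength = 0.6, noise_sd = 0,
                               profile = prof)
    g <- generate_strip(sp)
    r <- ratio_image(g$image)
    rp <- line_regions(center_box(sp$width, sp$height))
    mask <- build_mask(r, rp$control, list(rp$control, rp$test))
    expected <- matrix(0L, sp$height, sp$width)
    for (band in list(g$truth$control_rect, g$truth$test_rect)) {
      expected[(band$y0 + 1):band$y1, (band$x0 + 1):band$x1] <- 1L
    }
    expect_identical(mask$values, expected, info = prof)
  }
})

test_that("mask and threshold are invariant to exact channel rescaling", {
  sp <- synthetic_strip_spec(test_strength = 0.4, noise_sd = 0,
                             background = c(120, 120, 120),
                             band_color = c(100, 80, 80))
  img <- generate_strip(sp)$image
  scale2 <- rgb_image(img$red * 2L, img$green * 2L, img$blue * 2L)
  rp <- line_regions(center_box(sp$width, sp$height))
  m1 <- build_mask(ratio_image(img), rp$control, rp$test)
  m2 <- build_mask(ratio_image(scale2), rp$control, rp$test)
  expect_identical(m1$values, m2$values)
  expect_equal(m1$threshold, m2$threshold, tolerance = 1e-12)
})

test_that("mask is binary and zero outside the requested rectangles", {
  sp <- synthetic_strip_spec(test_strength = 0.8, noise_sd = 2)
  g <- generate_strip(sp)
  rp <- line_regions(center_box(sp$width, sp$height))
  mask <- build_mask(ratio_image(g$image), rp$control, rp$test)
  expect_true(all(mask$values %in% c(0L, 1L)))
  outside <- mask$values
  outside[(rp$test$y0 + 1):rp$test$y1, (rp$test$x0 + 1):rp$test$x1] <- 0L
  expect_true(all(outside == 0L))
})
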