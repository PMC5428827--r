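test_that("ROI thresholding applies the inclusive -100..200 HU window", {
  img <- array(0, c(3, 3, 1))
  msk <- array(TRUE, c(3, 3, 1))
  img[1, 1, 1] <- 250   # bone-like, above the window
  img[2, 1, 1] <- -100  # exactly on the lower bound: kept
  img[3, 1, 1] <- 200   # exactly on the upper bound: kept
  img[1, 2, 1] <- -101
  out <- threshold_roi(img, msk)
  expect_false(out[1, 1, 1])
  expect_true(out[2, 1, 1])
  expect_true(out[3, 1, 1])
  expect_false(out[1, 2, 1])
  # all-zero image: mask unchanged; result always a subset of the input
  expect_equal(threshold_roi(array(0, c(2, 2, 2)), array(TRUE, c(2, 2, 2))),
               array(TRUE, c(2, 2, 2)))
  expect_true(all(out | !out & !msk | msk))
  expect_true(all(!(out & !msk)))
  # empty result raises a classed error carrying context
  expect_error(threshold_roi(array(500, c(2, 2, 1)), array(TRUE, c(2, 2, 1)),
                             context = "P01 week 3"),
               class = "deltarad_empty_roi")
})

test_that("Butterworth smoothing is a unit-DC low-pass filter", {
  # constant image passes through exactly (only the DC component)
  const <- array(7, c(16, 16, 2))
  expect_equal(butterworth_smooth(const), const, tolerance = 1e-12)
  # pure high-frequency checkerboard: amplitude strictly reduced
  cb <- array(rep_len(c(1, -1), 16), c(16, 16, 1)) *
    rep(rep_len(c(1, -1), 16), each = 16)
  sm <- butterworth_smooth(cb)
  expect_lt(max(abs(sm)), max(abs(cb)))
  expect_gt(max(abs(sm)), 0)
  # white noise: output variance below input variance, mean preserved
  for (s in 1:10) {
    set.seed(s)
    img <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
    sm <- butterworth_smooth(img)
    expect_lt(var(as.numeric(sm)), var(as.numeric(img)))
    expect_equal(mean(sm), mean(img), tolerance = 1e-3 * abs(mean(img)) + 1e-9)
  }
  expect_error(butterworth_smooth(const, cutoff = 0), "cutoff")
})

test_that("smoothing matches the closed-form transfer function on sinusoids", {
  # a single-frequency wave must come back scaled by exactly H(f)
  n <- 64
  x <- seq_len(n) - 1
  for (k in c(2, 8, 20, 30)) {
    wave <- array(cos(2 * pi * k * x / n), c(n, n, 1)) # varies along dim 1
    sm <- butterworth_smooth(wave, order = 2, cutoff = 125)
    H <- 1 / sqrt(1 + ((k / n) / (125 / 512))^4)
    expect_equal(sm, wave * H, tolerance = 1e-8)
  }
})

test_that("smoothing is linear", {
  set.seed(3)
  a <- array(rnorm(16^2 * 2), c(16, 16, 2))
  b <- array(rnorm(16^2 * 2), c(16, 16, 2))
  expect_equal(butterworth_smooth(a + 2 * b),
               butterworth_smooth(a) + 2 * butterworth_smooth(b),
               tolerance = 1e-10)
})

test_that("bit-depth resampling maps the 12-bit HU range as documented", {
  # 8 bits -> 16 HU bins; range endpoints hit levels 0 and 255
  v <- array(c(-1024, -1009, -1008, 3071, 5000, -2000), c(6, 1, 1))
  lev <- resample_bit_depth(v)[, 1, 1]
  expect_equal(lev, c(0, 0, 1, 255, 255, 0))
  # two values 16 apart starting on a bin boundary land in adjacent bins
  expect_equal(diff(resample_bit_depth(array(c(-1024, -1008), c(2, 1, 1)))),
               array(1, c(1, 1, 1))[1])
  # monotone in HU, levels within [0, 2^bits - 1]
  set.seed(1)
  hu <- sort(runif(100, -1100, 3200))
  lv <- resample_bit_depth(array(hu, c(100, 1, 1)))
  expect_true(all(diff(as.numeric(lv)) >= 0))
  expect_true(all(lv >= 0 & lv <= 255))
  lv4 <- resample_bit_depth(array(hu, c(100, 1, 1)), bits = 4)
  expect_true(all(lv4 >= 0 & lv4 <= 15))
  expect_error(resample_bit_depth(v, bits = 0), "bits")
  expect_error(resample_bit_depth(v, bits = 17), "bits")
})

test_that("variant application runs threshold, then smooth, then resample", {
  set.seed(4)
  img <- array(rnorm(16 * 16 * 3, 50, 60), c(16, 16, 3))
  msk <- array(FALSE, c(16, 16, 3))
  msk[5:12, 5:12, ] <- TRUE
  raw <- apply_variant(img, msk, "raw")
  expect_equal(raw$image, img)             # raw: thresholding only
  expect_equal(raw$mask, threshold_roi(img, msk))
  both <- apply_variant(img, msk, "smooth_resample8")
  expect_equal(both$image,
               resample_bit_depth(butterworth_smooth(img)))
  expect_equal(both$mask, raw$mask)        # threshold from the raw image
  # constant in-range image: every variant sees a constant region
  cimg <- array(48, c(8, 8, 2))
  for (v in variant_ids()) {
    av <- apply_variant(cimg, array(TRUE, c(8, 8, 2)), v)
    expect_equal(length(unique(as.numeric(av$image))), 1)
  }
})

test_that("gray-level quantization uses 16 HU bins or native levels", {
  img <- array(c(-100, -85, -84, 200), c(4, 1, 1))
  q <- quantize_levels(img, "raw")
  expect_equal(q$n_levels, 19)
  expect_equal(as.numeric(q$levels), c(1, 1, 2, 19))
  q8 <- quantize_levels(resample_bit_depth(img), "resample8")
  expect_equal(q8$n_levels, 256)
  expect_true(all(q8$levels >= 1 & q8$levels <= 256))
})
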