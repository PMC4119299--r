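test_that("mSSIM is exactly one for identical images and decreases with noise", {
  x <- smooth_image(64)
  expect_equal(mean_ssim(x, x), 1)

  set.seed(3)
  vals <- vapply(c(0.05, 0.2, 0.5), function(s)
    mean_ssim(x + matrix(rnorm(64 * 64, sd = s), 64), x), 0)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals < 1))
})

test_that("mSSIM agrees with an independent reference implementation", {
  # frozen oracle: scikit-image structural_similarity (gaussian_weights=TRUE,
  # sigma=1.5, use_sample_covariance=FALSE, data_range=1) on this exact
  # fixture returns 0.5840224602
  x <- smooth_image(64, margin = 0, seed = 7)
  set.seed(7)  # restart the stream exactly as when freezing the oracle
  y <- x + matrix(rnorm(64 * 64, sd = 0.1), 64)
  expect_equal(mean_ssim(x, y), 0.5840224602, tolerance = 1e-8)
})

test_that("mSSIM is symmetric and invariant to joint affine rescaling", {
  x <- smooth_image(48, seed = 5)
  set.seed(5)
  y <- x + matrix(rnorm(48 * 48, sd = 0.2), 48)
  expect_lt(abs(mean_ssim(x, y, dynamic_range = 1) -
                mean_ssim(y, x, dynamic_range = 1)), 1e-10)
  # joint rescaling of both images cancels in the reference normalization
  expect_equal(mean_ssim(3 * x + 2, 3 * y + 2), mean_ssim(x, y),
               tolerance = 1e-9)
  expect_error(mean_ssim(x, matrix(0, 10, 10)), "differ")
})

test_that("mutual information reproduces entropies and independence", {
  x <- smooth_image(64)
  expect_equal(mutual_information(x, x, bins = 32),
               binned_entropy(x, 32))

  set.seed(9)
  a <- matrix(runif(256 * 256), 256)
  b <- matrix(runif(256 * 256), 256)
  expect_lt(mutual_information(a, b, bins = 64), 0.05)

  expect_equal(mutual_information(matrix(1, 16, 16), matrix(1, 16, 16)), 0)
})

test_that("mutual information agrees with an independent reference implementation", {
  # frozen oracle: numpy joint-histogram MI (32 bins, base 2) on this exact
  # fixture returns 1.3581579148
  x <- smooth_image(64, margin = 0, seed = 7)
  set.seed(7)
  y <- x + matrix(rnorm(64 * 64, sd = 0.1), 64)
  expect_equal(mutual_information(x, y, bins = 32), 1.3581579148,
               tolerance = 1e-8)
})

test_that("mutual information is symmetric and noise never increases it", {
  x <- smooth_image(48, seed = 5)
  set.seed(5)
  y <- x + matrix(rnorm(48 * 48, sd = 0.2), 48)
  expect_lt(abs(mutual_information(x, y) - mutual_information(y, x)), 1e-10)

  set.seed(13)
  mis <- vapply(c(0, 0.1, 0.4), function(s)
    mutual_information(x + matrix(rnorm(48 * 48, sd = s), 48), y, bins = 32),
    0)
  expect_true(all(diff(mis) < 0.05))  # monotone up to statistical jitter
})

test_that("slice evaluation tabulates both metrics per slice", {
  st <- array(0, c(32, 32, 2))
  st[, , 1] <- smooth_image(32, margin = 4)
  st[, , 2] <- smooth_image(32, margin = 4, seed = 2)
  ev <- evaluate_slices(st, st)
  expect_identical(names(ev), c("slice", "mssim", "mi"))
  expect_equal(ev$mssim, c(1, 1))
  expect_equal(ev$mi[1], binned_entropy(st[, , 1], 256))
})
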