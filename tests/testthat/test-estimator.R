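test_that("background subtraction removes the margin mean", {
  const <- matrix(5, 32, 32)
  expect_equal(subtract_background(const), matrix(0, 32, 32))

  img <- smooth_image(64, margin = 12)
  expect_equal(subtract_background(img, 0.05), img)

  shifted <- img + 3
  out <- subtract_background(shifted, 0.05)
  expect_lt(abs(mean(out[, c(1:3, 62:64)])), 1e-12)
  expect_equal(out, img, tolerance = 1e-12)
  expect_error(subtract_background(matrix(0, 4, 2), 0.5), "degenerate")
})

test_that("shift profile is zero for identical images and exact for integer shifts", {
  img <- subtract_background(smooth_image(64))
  pr <- rowwise_shift_profile(img, img)
  expect_true(all(abs(pr$t_m) < 1e-9))
  expect_true(all(pr$peak_corr > 1 - 1e-9))

  sh <- apply_planar_transform(img, planar_transform(
    matrix(c(1, 0, 0, 0, 1, 0, -3, 0, 1), 3, 3)))  # content moves -3 in x
  pr3 <- rowwise_shift_profile(img, sh, axis_control(subpixel = FALSE))
  expect_true(all(pr3$t_m == 3))
})

test_that("row-wise peak positions equal a brute-force lag search", {
  img <- subtract_background(smooth_image(64, seed = 11))
  sh <- apply_planar_transform(img, planar_transform(
    matrix(c(1, 0, 0, 0, 1, 0, 5, 0, 1), 3, 3)))
  ctl <- axis_control(subpixel = FALSE)
  pr <- rowwise_shift_profile(img, sh, ctl)
  maxs <- floor(ctl$max_shift_frac * 64)
  for (q in seq_along(pr$rows)) {
    r <- pr$rows[q]
    expect_identical(pr$t_m[q],
                     as.numeric(brute_force_row_lag(img[r, ], sh[r, ], maxs)))
  }
})

test_that("subpixel refinement resolves a half-pixel shift", {
  x <- seq_len(64) - 32.5
  p0 <- t(vapply(seq_len(48), function(r)
    exp(-(x - 3)^2 / (2 * 4^2)) * (1 + 0.3 * sin(r / 3)), numeric(64)))
  moved <- t(vapply(seq_len(48), function(r)
    exp(-(x - 3.5)^2 / (2 * 4^2)) * (1 + 0.3 * sin(r / 3)), numeric(64)))
  pr <- rowwise_shift_profile(p0, moved, axis_control())
  # content moved +0.5 px, so P0 must be probed at x - 0.5: t_m = -0.5
  expect_true(all(abs(pr$t_m + 0.5) < 0.05))
})

test_that("degenerate rows yield an informative error", {
  z <- matrix(0, 32, 32)
  expect_error(rowwise_shift_profile(z, z), "insufficient signal")
})

test_that("shift-line fit recovers exact and noisy linear laws", {
  pr <- structure(list(y = seq(-40, 40, by = 2),
                       t_m = rep(4, 41),
                       peak_corr = rep(1, 41)), class = "shift_profile")
  f <- fit_shift_line(pr)
  expect_equal(c(f$slope, f$intercept, f$residual_rms), c(0, 4, 0),
               tolerance = 1e-12)

  pr$t_m <- -0.1 * pr$y
  f <- fit_shift_line(pr)
  expect_equal(f$slope, -0.1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)

  set.seed(42)
  y <- seq(-99.5, 99.5, by = 1)
  t_m <- 2 + 0.05 * y + rnorm(200, sd = 0.1)
  f <- fit_shift_line(structure(list(y = y, t_m = t_m,
                                     peak_corr = rep(1, 200)),
                                class = "shift_profile"))
  se_slope <- 0.1 / sqrt(sum((y - mean(y))^2))
  expect_lt(abs(f$slope - 0.05), 3 * se_slope)
  expect_lt(abs(f$intercept - 2), 3 * 0.1 / sqrt(200))

  expect_error(fit_shift_line(structure(list(y = c(1, 1), t_m = c(0, 0),
                                             peak_corr = c(1, 1)),
                                        class = "shift_profile")),
               "distinct rows")
})

test_that("estimate updates invert the linear shift law", {
  u <- update_estimate(axis_params(0, 0), slope = 0, intercept = 4)
  expect_equal(c(u$theta, u$delta), c(0, 2))

  # slope of 2 * 5 degrees (in radians) maps to theta = -5 degrees
  u <- update_estimate(axis_params(0, 0), slope = 2 * 5 * pi / 180,
                       intercept = 0)
  expect_equal(u$theta, -5, tolerance = 0.01)
  expect_equal(u$delta, 0)

  u <- update_estimate(axis_params(-4, 1.5), slope = 0, intercept = 1)
  expect_equal(c(u$theta, u$delta), c(-4, 2))

  expect_error(update_estimate(axis_params(0, 0), slope = 10, intercept = 0),
               "diverged")
})

test_that("an exactly mirrored pair estimates zero parameters in one iteration", {
  s <- phantom_pair(64)
  fit <- estimate_axis(projection_at(s, 0), projection_at(s, 180))
  expect_true(fit$converged)
  expect_identical(fit$iterations, 1L)
  expect_lt(abs(fit$params$theta), 0.01)
  expect_lt(abs(fit$params$delta), 0.05)
})

test_that("a pure translation is recovered in at most two iterations", {
  s <- phantom_pair(128)
  m <- inject_misalignment(s, axis_params(0, 3.2))
  fit <- estimate_axis(projection_at(m, 0), projection_at(m, 180))
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2L)
  expect_lt(abs(fit$params$delta - 3.2), 0.1)
  expect_lt(abs(fit$params$theta), 0.05)
})

test_that("the reference misalignment is recovered on the half-size phantom", {
  s <- phantom_pair(128)
  m <- inject_misalignment(s, axis_params(-5, 2))
  fit <- estimate_axis(projection_at(m, 0), projection_at(m, 180))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$theta + 5), 0.25)
  expect_lt(abs(fit$params$delta - 2), 0.5)

  # refinement: the final shift-line residual is no worse than the first
  expect_lte(fit$trace$residual_rms[fit$iterations],
             fit$trace$residual_rms[1] + 1e-6)
})

test_that("re-estimating an already corrected pair returns near-zero parameters", {
  s <- phantom_pair(128)
  m <- inject_misalignment(s, axis_params(-5, 2))
  fit <- estimate_axis(projection_at(m, 0), projection_at(m, 180))
  corr <- correct_series(m, fit$params)
  fit2 <- estimate_axis(projection_at(corr, 0), projection_at(corr, 180))
  expect_lt(abs(fit2$params$theta), 0.15)
  expect_lt(abs(fit2$params$delta), 0.10)
})

test_that("non-convergence at max_iter is flagged, not silent", {
  s <- phantom_pair(128)
  m <- inject_misalignment(s, axis_params(-5, 2))
  expect_warning(
    fit <- estimate_axis(projection_at(m, 0), projection_at(m, 180),
                         axis_control(max_iter = 1)),
    "did not converge")
  expect_false(fit$converged)
  expect_identical(fit$iterations, 1L)
})

test_that("fit methods expose coefficients, fitted values and residuals", {
  s <- phantom_pair(64)
  m <- inject_misalignment(s, axis_params(2, -1))
  fit <- estimate_axis(projection_at(m, 0), projection_at(m, 180))
  co <- coef(fit)
  expect_named(co, c("theta", "delta"))
  expect_equal(length(fitted(fit)), length(fit$profile$rows))
  expect_equal(residuals(fit), fit$profile$t_m - fitted(fit))
  expect_output(print(fit), "theta")
  expect_output(print(summary(fit)), "Iteration trace")
})

test_that("control parameters are validated", {
  expect_error(axis_control(max_iter = 0))
  expect_error(axis_control(tol_theta = -1))
  expect_error(axis_control(row_margin_frac = 0.5), "0.45")
})
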