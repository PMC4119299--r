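test_that("mirror transform reduces to known closed forms", {
  m0 <- mirror_transform(axis_params(0, 0))$matrix
  expect_equal(m0, diag(c(-1, 1, 1)))

  # offset only: x' = -x + 2 delta, y' = y
  m2 <- mirror_transform(axis_params(0, 2))$matrix
  p <- m2 %*% c(3, 7, 1)
  expect_equal(p[1], 1)
  expect_equal(p[2], 7)
  expect_equal(m2[1, 3], 4)
})

test_that("mirror and correction transforms are involutions with det -1", {
  for (th in seq(-40, 40, by = 8)) {
    for (dl in seq(-10, 10, by = 5)) {
      p <- axis_params(th, dl)
      for (m in list(mirror_transform(p)$matrix,
                     correction_transform(p)$matrix)) {
        expect_lt(max(abs(m %*% m - diag(3))), 1e-10)
        expect_equal(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1], -1,
                     tolerance = 1e-10)
        expect_identical(m[3, ], c(0, 0, 1))
      }
    }
  }
})

test_that("correction transform matches its explicit factor product", {
  th <- 3 * pi / 180; dl <- 1.5
  tr <- function(d) matrix(c(1, 0, 0, 0, 1, 0, d, 0, 1), 3, 3)
  rot <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                              0, 0, 1), 3, 3)
  # translate axis to centre, reflect, rotate by -2 theta, translate back
  oracle4 <- tr(dl) %*% diag(c(-1, 1, 1)) %*% rot(-2 * th) %*% tr(-dl)
  # five-factor mirror composite about the same axis
  oracle5 <- tr(dl) %*% rot(th) %*% diag(c(-1, 1, 1)) %*% rot(-th) %*% tr(-dl)
  got <- correction_transform(axis_params(3, 1.5))$matrix
  expect_lt(max(abs(got - oracle4)), 1e-12)
  expect_lt(max(abs(got - oracle5)), 1e-12)
  expect_lt(max(abs(mirror_transform(axis_params(3, 1.5))$matrix - oracle5)),
            1e-12)
})

test_that("small-angle mirror map matches examples and is second-order accurate", {
  p0 <- small_angle_mirror(axis_params(0, 0), 3, 7)
  expect_equal(c(p0$x, p0$y), c(-3, 7))
  p2 <- small_angle_mirror(axis_params(0, 2), 3, 7)
  expect_equal(c(p2$x, p2$y), c(1, 7))

  # error vs the exact matrix shrinks quadratically in theta
  grid <- expand.grid(x = seq(-128, 128, by = 32), y = seq(-128, 128, by = 32))
  thetas <- c(0.25, 0.5, 1, 2, 4, 8)  # degrees
  errs <- vapply(thetas, function(th) {
    p <- axis_params(th, 1)
    m <- mirror_transform(p)$matrix
    exact <- m %*% rbind(grid$x, grid$y, 1)
    approx <- small_angle_mirror(p, grid$x, grid$y)
    max(abs(exact[1, ] - approx$x), abs(exact[2, ] - approx$y))
  }, 0)
  slope <- coef(lm(log(errs) ~ log(thetas * pi / 180)))[2]
  expect_equal(unname(slope), 2, tolerance = 0.1)
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(axis_params(50, 0), "45")
  expect_error(axis_params(NA, 0), "finite")
  expect_error(axis_params(0, Inf), "finite")
  expect_error(planar_transform(matrix(0, 3, 3)), "bottom row")
  bad <- diag(3); bad[1, 1] <- 0; bad[2, 2] <- 0
  expect_error(planar_transform(bad), "invertible")
})

test_that("planar resampling is exact for identity, integer shifts and reflections", {
  img <- smooth_image(64)
  expect_identical(apply_planar_transform(img, planar_transform(diag(3))), img)

  # +3 px along x equals an index shift (support is clear of the borders)
  sh <- matrix(c(1, 0, 0, 0, 1, 0, 3, 0, 1), 3, 3)
  out <- apply_planar_transform(img, planar_transform(sh))
  expect_equal(out[, 4:64], img[, 1:61])
  expect_true(all(out[, 1:3] == 0))

  # reflecting twice restores the original exactly
  refl <- planar_transform(diag(c(-1, 1, 1)))
  back <- apply_planar_transform(apply_planar_transform(img, refl), refl)
  expect_equal(back, img)
})
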