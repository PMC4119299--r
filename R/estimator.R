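#' Control parameters for the axis estimator
#'
#' @param max_iter Maximum number of refinement iterations (>= 1).
#' @param tol_theta Convergence tolerance on the flip-angle increment,
#'   degrees.
#' @param tol_delta Convergence tolerance on the offset increment, pixels.
#' @param row_margin_frac Fraction of the image height excluded at the top
#'   and bottom before row-wise correlation (rows near the border lose
#'   support under the reflective resampling).
#' @param min_peak_corr Minimum normalized peak correlation for a row to be
#'   kept in the linear fit.
#' @param max_shift_frac Fraction of the image width bounding the
#'   correlation lag search on each side.
#' @param subpixel Refine the integer correlation peak by 3-point parabolic
#'   interpolation.
#' @param background_margin_frac Fraction of the width used as left/right
#'   background strips by [subtract_background()].
#' @param weighted Weight the linear fit by the per-row peak correlation
#'   (clipped to `[0, 1]`); set `FALSE` for a plain unweighted fit.
#' @param interp Interpolation used for the reflective resampling. The
#'   default `"bicubic"` roughly halves the resampling-blur bias of the
#'   shift measurement relative to `"bilinear"`.
#' @param accelerate Apply an adaptive gain to the flip-angle update. The
#'   row-wise shift measurement systematically under-reports a residual
#'   rotation (the rotation's vertical shear mixes neighbouring rows), so
#'   the plain iteration contracts slowly; a secant estimate of the damping
#'   factor from successive increments restores fast convergence to the
#'   same fixed point. `FALSE` reproduces the plain scheme.
#' @return A list of class `"axis_control"`.
#' @export
axis_control <- function(max_iter = 20L, tol_theta = 0.01, tol_delta = 0.05,
                         row_margin_frac = 0.1, min_peak_corr = 0.3,
                         max_shift_frac = 0.25, subpixel = TRUE,
                         background_margin_frac = 0.05, weighted = TRUE,
                         interp = "bicubic", accelerate = TRUE) {
  stopifnot(max_iter >= 1, tol_theta > 0, tol_delta > 0)
  for (f in c(row_margin_frac, min_peak_corr, max_shift_frac,
              background_margin_frac))
    if (!is.finite(f)) stop("control fractions must be finite")
  if (row_margin_frac <= 0 || row_margin_frac >= 0.45 ||
      max_shift_frac <= 0 || max_shift_frac >= 0.45 ||
      background_margin_frac <= 0 || background_margin_frac >= 0.45)
    stop("control fractions must lie in (0, 0.45)")
  structure(list(max_iter = as.integer(max_iter), tol_theta = tol_theta,
                 tol_delta = tol_delta, row_margin_frac = row_margin_frac,
                 min_peak_corr = min_peak_corr,
                 max_shift_frac = max_shift_frac,
                 subpixel = isTRUE(subpixel),
                 background_margin_frac = background_margin_frac,
                 weighted = isTRUE(weighted), interp = interp,
                 accelerate = isTRUE(accelerate)),
            class = "axis_control")
}

#' Subtract the mean of the background margins
#'
#' Subtracts the mean over the left and right margin-column strips from the
#' whole image, so that air regions sit at zero before correlation.
#'
#' @param image Numeric matrix.
#' @param margin_frac Fraction of the width used as each strip (at least one
#'   column per side).
#' @return The background-subtracted image.
#' @export
subtract_background <- function(image, margin_frac = 0.05) {
  stopifnot(is.matrix(image), is.numeric(image))
  w <- ncol(image)
  k <- floor(margin_frac * w)
  if (k < 1) k <- 1L
  if (2 * k >= w) stop("degenerate background margin")
  image - mean(image[, c(seq_len(k), seq(w - k + 1L, w))])
}

#' Row-wise cross-correlation shift profile
#'
#' For each retained detector row, computes the zero-normalized
#' cross-correlation between the row of `p0` and the row of the reflected
#' 180 degree frame `ppik` over lags `|t| <= max_shift`, and records the lag
#' of the correlation maximum (the per-row shift `t_m(y)`) together with the
#' normalized peak correlation. `t_m` is defined so that
#' `p0(x + t_m, y) ~ ppik(x, y)`: under a residual misalignment
#' `(theta - theta_est, delta - delta_est)` it follows the linear law
#' `t_m(y) = 2(delta - delta_est) - 2(theta - theta_est) y`.
#'
#' Rows in the top/bottom margin, rows with peak correlation below
#' `min_peak_corr`, rows with (near-)constant intensity and rows whose
#' maximum sits on the boundary of the lag search are excluded.
#'
#' @param p0 The 0 degree projection (background-subtracted matrix).
#' @param ppik The reflected/corrected 180 degree projection, same shape.
#' @param control An [axis_control()].
#' @return An object of class `"shift_profile"`: list with `rows` (1-based
#'   row indices kept), `y` (centred row coordinate), `t_m` (pixels,
#'   subpixel), `peak_corr`, and the image dimensions.
#' @export
rowwise_shift_profile <- function(p0, ppik, control = axis_control()) {
  stopifnot(is.matrix(p0), is.matrix(ppik))
  if (!identical(dim(p0), dim(ppik))) stop("projection shapes differ")
  h <- nrow(p0); w <- ncol(p0)
  if (h < 16 || w < 16) stop("projections must be at least 16 x 16")
  margin <- floor(control$row_margin_frac * h)
  rows <- seq.int(margin + 1L, h - margin)
  maxs <- max(1L, floor(control$max_shift_frac * w))
  lags <- seq.int(-maxs, maxs)
  a <- p0[rows, , drop = FALSE]
  b <- ppik[rows, , drop = FALSE]
  nr <- length(rows)
  cc <- matrix(NA_real_, nr, length(lags))
  for (li in seq_along(lags)) {
    t0 <- lags[li]
    j0 <- max(1L, 1L - t0); j1 <- min(w, w - t0)
    nn <- j1 - j0 + 1L
    if (nn < 8L) next
    u <- a[, (j0 + t0):(j1 + t0), drop = FALSE]
    v <- b[, j0:j1, drop = FALSE]
    su <- rowSums(u); sv <- rowSums(v)
    num <- rowSums(u * v) - su * sv / nn
    du <- rowSums(u * u) - su^2 / nn
    dv <- rowSums(v * v) - sv^2 / nn
    den <- sqrt(pmax(du, 0) * pmax(dv, 0))
    ok <- den > 1e-12 * nn
    cc[ok, li] <- num[ok] / den[ok]
  }
  best <- apply(cc, 1L, function(z) if (all(is.na(z))) NA_integer_
                else which.max(z))
  keep <- !is.na(best)
  # reject boundary maxima and weak peaks
  pk <- rep(NA_real_, nr)
  pk[keep] <- cc[cbind(which(keep), best[keep])]
  keep <- keep & !is.na(pk) & pk >= control$min_peak_corr &
    best > 1L & best < length(lags)
  if (!any(keep)) stop("insufficient signal: no usable rows")
  idx <- which(keep)
  tm <- numeric(length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]; j <- best[i]
    t0 <- lags[j]
    if (control$subpixel) {
      cm <- cc[i, j - 1L]; c0 <- cc[i, j]; cp <- cc[i, j + 1L]
      if (is.finite(cm) && is.finite(cp)) {
        d2 <- cm - 2 * c0 + cp
        off <- if (d2 < 0) 0.5 * (cm - cp) / d2 else 0
        if (abs(off) <= 1) t0 <- t0 + off
      }
    }
    tm[q] <- t0
  }
  structure(list(rows = rows[idx],
                 y = rows[idx] - (h + 1) / 2,
                 t_m = tm,
                 peak_corr = pk[idx],
                 height = h, width = w,
                 max_shift = maxs),
            class = "shift_profile")
}

#' @export
print.shift_profile <- function(x, ...) {
  cat(sprintf(
    "shift profile: %d rows, t_m in [%.3f, %.3f] px, mean peak corr %.3f\n",
    length(x$rows), min(x$t_m), max(x$t_m), mean(x$peak_corr)))
  invisible(x)
}

#' Fit the linear shift model
#'
#' Weighted least-squares fit of `t_m(y) = intercept + slope * y` with the
#' row coordinate `y` measured from the image centre and weights equal to
#' the per-row peak correlations clipped to `[0, 1]` (or 1 when unweighted).
#'
#' @param profile A [rowwise_shift_profile()] result.
#' @param weighted Use peak-correlation weights.
#' @return List with `slope` (pixels per pixel), `intercept` (pixels) and
#'   `residual_rms` (weighted RMS of the fit residuals, pixels).
#' @export
fit_shift_line <- function(profile, weighted = TRUE) {
  y <- profile$y; t_m <- profile$t_m
  if (length(y) < 2L || length(unique(y)) < 2L)
    stop("need at least two distinct rows to fit the shift line")
  w <- if (weighted) pmin(pmax(profile$peak_corr, 0), 1) else rep(1, length(y))
  if (sum(w) <= 0) w <- rep(1, length(y))
  fit <- stats::lm.wfit(cbind(1, y), t_m, w)
  res <- fit$residuals
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       residual_rms = sqrt(sum(w * res^2) / sum(w)))
}

#' Update the axis estimate from a fitted shift line
#'
#' Inverts the linear law `t_m(y) = 2(delta - delta_est) -
#' 2(theta - theta_est) y`: the offset estimate increases by half the
#' intercept and the angle estimate decreases by half the slope (a
#' dimensionless pixel-per-pixel slope, i.e. radians, converted to degrees).
#'
#' @param prev Current [axis_params()] estimate.
#' @param slope,intercept Fitted shift-line coefficients.
#' @return The updated [axis_params()].
#' @export
update_estimate <- function(prev, slope, intercept) {
  if (!is.finite(slope) || !is.finite(intercept))
    stop("non-finite shift-line fit")
  p <- axis_params(prev$theta, prev$delta)
  theta <- p$theta - (slope / 2) * 180 / pi
  delta <- p$delta + intercept / 2
  out <- tryCatch(axis_params(theta, delta), error = function(e) NULL)
  if (is.null(out)) stop("diverged: updated parameters out of range")
  out
}

#' Estimate the rotation-axis misalignment from the 0/180 degree pair
#'
#' The package's central fitter. Both projections are background-subtracted,
#' then the scheme iterates: (i) reflect the 180 degree frame about the
#' current axis estimate ([correction_transform()] applied through
#' [apply_planar_transform()]); (ii) measure the remaining per-row shift
#' against the 0 degree frame ([rowwise_shift_profile()]); (iii) fit the
#' linear shift law ([fit_shift_line()]) and update the estimate
#' ([update_estimate()]). Because a residual rotation is under-reported by
#' row-wise correlation (its vertical shear mixes rows), the flip-angle
#' update is by default rescaled by a secant estimate of that damping
#' factor (see `accelerate` in [axis_control()]); the fixed point is
#' unchanged. Iteration stops when both applied parameter steps fall below
#' the tolerances, or flags non-convergence at `max_iter`.
#'
#' @param p0 The 0 degree projection (numeric matrix, rows = detector y).
#' @param ppi The 180 degree projection, same shape.
#' @param control An [axis_control()].
#' @return An object of class `"axis_fit"` with components `params`
#'   ([axis_params()]), `trace` (per-iteration data frame: estimates,
#'   shift-line coefficients, residual RMS, mean peak correlation, rows
#'   retained), `converged`, `iterations`, `profile` and `fit` from the last
#'   iteration, `control` and `dim`. Supports `coef()`, `print()`,
#'   `summary()`, `plot()`, `fitted()` and `residuals()`.
#' @examples
#' vol <- shepp_logan_3d(64)
#' s <- simulate_tilt_series(vol, c(0, 180))
#' s <- inject_misalignment(s, axis_params(-3, 1.5))
#' fit <- estimate_axis(projection_at(s, 0), projection_at(s, 180))
#' coef(fit)
#' @export
estimate_axis <- function(p0, ppi, control = axis_control()) {
  stopifnot(inherits(control, "axis_control"))
  if (!is.matrix(p0) || !is.matrix(ppi) || !identical(dim(p0), dim(ppi)))
    stop("'p0' and 'ppi' must be numeric matrices of identical shape")
  if (nrow(p0) < 16 || ncol(p0) < 16)
    stop("projections must be at least 16 x 16")
  w <- ncol(p0)
  p0b <- subtract_background(p0, control$background_margin_frac)
  ppib <- subtract_background(ppi, control$background_margin_frac)
  cur <- axis_params(0, 0)
  trace <- vector("list", control$max_iter)
  converged <- FALSE
  profile <- NULL; fit <- NULL
  d_prev <- NULL; step_prev <- NULL
  for (k in seq_len(control$max_iter)) {
    tk <- correction_transform(cur)
    ppik <- apply_planar_transform(ppib, tk, interp = control$interp)
    profile <- rowwise_shift_profile(p0b, ppik, control)
    fit <- fit_shift_line(profile, weighted = control$weighted)
    d_delta <- fit$intercept / 2
    d_theta <- -(fit$slope / 2) * 180 / pi
    step <- d_theta
    if (control$accelerate && !is.null(d_prev) && abs(step_prev) > 1e-12) {
      # secant estimate of the measurement damping factor; the applied step
      # approximates the full residual d_theta / c
      c_hat <- (d_prev - d_theta) / step_prev
      if (is.finite(c_hat) && c_hat > 0.15 && c_hat < 1.2)
        step <- d_theta / c_hat
      cap <- 5 * max(abs(d_theta), 2 * control$tol_theta)
      if (abs(step) > cap) step <- sign(step) * cap
    }
    d_prev <- d_theta; step_prev <- step
    cur <- update_estimate(cur, -step * 2 * pi / 180, fit$intercept)
    if (abs(cur$delta) >= w / 4)
      stop("diverged: offset estimate exceeds a quarter of the image width")
    trace[[k]] <- data.frame(
      iter = k, theta = cur$theta, delta = cur$delta,
      d_theta = d_theta, d_delta = d_delta, step_theta = step,
      slope = fit$slope, intercept = fit$intercept,
      residual_rms = fit$residual_rms,
      mean_peak_corr = mean(profile$peak_corr),
      n_rows = length(profile$rows))
    if (abs(step) < control$tol_theta && abs(d_delta) < control$tol_delta) {
      converged <- TRUE
      break
    }
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, TRUE)])
  if (!converged)
    warning(sprintf("estimate_axis did not converge in %d iterations",
                    control$max_iter))
  structure(list(params = cur, trace = trace, converged = converged,
                 iterations = nrow(trace), profile = profile, fit = fit,
                 control = control, dim = dim(p0), call = match.call()),
            class = "axis_fit")
}
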