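#' @export
coef.axis_fit <- function(object, ...) {
  c(theta = object$params$theta, delta = object$params$delta)
}

#' @export
print.axis_fit <- function(x, digits = 4, ...) {
  cat("Rotation-axis misalignment fit (0/180 degree mirror symmetry)\n")
  cat(sprintf("  theta: %s deg   delta: %s px\n",
              format(x$params$theta, digits = digits),
              format(x$params$delta, digits = digits)))
  cat(sprintf("  %d iteration%s, %sconverged\n", x$iterations,
              if (x$iterations == 1) "" else "s",
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
summary.axis_fit <- function(object, ...) {
  structure(list(params = object$params, trace = object$trace,
                 converged = object$converged,
                 iterations = object$iterations,
                 n_rows = length(object$profile$rows),
                 residual_rms = object$fit$residual_rms,
                 mean_peak_corr = mean(object$profile$peak_corr),
                 dim = object$dim),
            class = "summary.axis_fit")
}

#' @export
print.summary.axis_fit <- function(x, ...) {
  cat("Rotation-axis misalignment fit\n")
  cat(sprintf("  projections: %d x %d px\n", x$dim[1], x$dim[2]))
  cat(sprintf("  theta = %.4f deg, delta = %.4f px (%sconverged, %d iter)\n",
              x$params$theta, x$params$delta,
              if (x$converged) "" else "NOT ", x$iterations))
  cat(sprintf("  final fit: %d rows, residual RMS %.4f px, mean peak corr %.3f\n",
              x$n_rows, x$residual_rms, x$mean_peak_corr))
  cat("\nIteration trace:\n")
  print(x$trace[, c("iter", "theta", "delta", "d_theta", "d_delta",
                    "residual_rms", "mean_peak_corr", "n_rows")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predicted per-row shifts of the final iteration
#' @param object An `"axis_fit"`.
#' @param ... Unused.
#' @return Fitted values of the shift line at the retained rows.
#' @export
fitted.axis_fit <- function(object, ...) {
  object$fit$intercept + object$fit$slope * object$profile$y
}

#' @export
residuals.axis_fit <- function(object, ...) {
  object$profile$t_m - fitted(object)
}

#' Diagnostic plot for an axis fit
#'
#' Left: the final row-wise shift profile `t_m(y)` with the fitted line
#' (residual slope/intercept are near zero once converged). Right: the
#' parameter estimates across iterations.
#'
#' @param x An `"axis_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.axis_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$profile$y, x$profile$t_m, pch = 20, cex = 0.5,
       xlab = "row y (centred, px)", ylab = expression(t[m](y) ~ "(px)"),
       main = "final shift profile", ...)
  abline(a = x$fit$intercept, b = x$fit$slope, col = 2, lwd = 2)
  tr <- x$trace
  plot(tr$iter, tr$theta, type = "b", pch = 19, col = 2,
       xlab = "iteration", ylab = "estimate",
       ylim = range(c(tr$theta, tr$delta)), main = "iteration trace")
  lines(tr$iter, tr$delta, type = "b", pch = 17, col = 4)
  legend("right", legend = c(expression(hat(theta) ~ "(deg)"),
                             expression(hat(delta) ~ "(px)")),
         col = c(2, 4), pch = c(19, 17), bty = "n")
  invisible(x)
}
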