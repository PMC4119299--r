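#' Mass-center (MC) sinogram correction baseline
#'
#' The classical translational alignment scheme used by phase-contrast CT
#' reconstruction suites: the intensity-weighted center of mass of each
#' projection along the detector x direction traces a sinusoid
#' `m(alpha) = A cos(alpha) + B sin(alpha) + c` over the tilt angles; `c` is
#' the apparent position of the rotation axis, and every projection is
#' translated by `-c` so the axis lands on the detector centre line. The
#' correction is purely translational: it removes an axis offset but cannot
#' compensate an in-plane flip angle.
#'
#' @param series A [tilt_series()]; projections should be
#'   background-subtracted and carry nonnegative total mass.
#' @param interp Interpolation passed to [apply_planar_transform()].
#' @return The corrected [tilt_series()], with attributes `"mc_center"`
#'   (the fitted `c`, pixels from the detector centre) and `"mc_fit"` (the
#'   fitted `A`, `B`, `c`).
#' @export
mc_correct <- function(series, interp = "bilinear") {
  stopifnot(inherits(series, "tilt_series"))
  d <- dim(series$projections)
  xc <- seq_len(d[2]) - (d[2] + 1) / 2
  mass <- apply(series$projections, 3, sum)
  if (any(mass <= 1e-8 * max(abs(mass))))
    stop("near-zero total mass in a projection; cannot locate mass center")
  mx <- vapply(seq_len(d[3]), function(i)
    sum(colSums(series$projections[, , i]) * xc) / mass[i], 0)
  a <- series$angles * pi / 180
  fit <- stats::lm.fit(cbind(cosa = cos(a), sina = sin(a), c = 1), mx)
  cen <- unname(fit$coefficients["c"])
  out <- series
  if (abs(cen) > 1e-9) {
    fwd <- planar_transform(.trans3(-cen))
    proj <- series$projections
    for (i in seq_len(d[3]))
      proj[, , i] <- apply_planar_transform(series$projections[, , i], fwd,
                                            interp = interp)
    out <- tilt_series(proj, series$angles)
  }
  attr(out, "mc_center") <- cen
  attr(out, "mc_fit") <- fit$coefficients
  out
}
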