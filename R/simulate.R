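#' Tilt series container
#'
#' A stack of 2D projections with their tilt angles. Projections are stored
#' as an `H x W x n_angles` array (rows = detector y, columns = detector x),
#' one projection per angle, angles ascending in `[0, 180]` degrees.
#'
#' @param projections `H x W x n` numeric array, or a list of equally sized
#'   matrices.
#' @param angles Numeric vector of tilt angles in degrees, one per
#'   projection.
#' @return An object of class `"tilt_series"` with elements `projections`
#'   and `angles`.
#' @export
tilt_series <- function(projections, angles) {
  if (is.list(projections)) {
    d <- dim(projections[[1]])
    if (!all(vapply(projections, function(m) identical(dim(m), d), TRUE)))
      stop("all projections must have the same shape")
    projections <- array(unlist(projections), c(d, length(projections)))
  }
  if (!is.array(projections) || length(dim(projections)) != 3L)
    stop("'projections' must be an H x W x n array")
  angles <- as.numeric(angles)
  if (length(angles) != dim(projections)[3])
    stop("need exactly one projection per angle")
  if (is.unsorted(angles) || any(angles < 0) || any(angles > 180))
    stop("'angles' must be ascending within [0, 180] degrees")
  if (!all(is.finite(projections))) stop("projections must be finite")
  structure(list(projections = projections, angles = angles),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$projections)
  cat(sprintf("tilt series: %d projections of %d x %d px, angles %g..%g deg\n",
              d[3], d[1], d[2], min(x$angles), max(x$angles)))
  invisible(x)
}

#' Extract the projection at a given tilt angle
#'
#' @param series A [tilt_series()].
#' @param angle Tilt angle in degrees; must match a stored angle within
#'   `tol`.
#' @param tol Matching tolerance in degrees.
#' @return The projection matrix.
#' @export
projection_at <- function(series, angle, tol = 1e-6) {
  i <- which(abs(series$angles - angle) <= tol)
  if (length(i) != 1L)
    stop(sprintf("no unique projection at %g degrees", angle))
  series$projections[, , i]
}

#' Simulate a parallel-beam tilt series
#'
#' Parallel-beam line integrals of a volume: for each axial slice of the
#' volume, the 1D projection at each tilt angle (the Radon transform of that
#' slice, sampled with unit steps and bilinear in-plane interpolation),
#' assembled into 2D projections with the rotation axis passing exactly
#' through the volume and detector centres. With this geometry the 180
#' degree projection is the x-mirror of the 0 degree projection, the
#' symmetry the axis estimator relies on. Fully deterministic.
#'
#' @param volume An `n x n x n` array as returned by [shepp_logan_3d()]
#'   (indexed `[axial, x, y]`).
#' @param angles Tilt angles in degrees, ascending in `[0, 180]`. Default:
#'   181 projections at 1 degree steps.
#' @param width Detector width in pixels; defaults to the volume side.
#' @return A [tilt_series()] of `n x width` projections.
#' @export
simulate_tilt_series <- function(volume, angles = seq(0, 180, by = 1),
                                 width = NULL) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("'volume' must be a 3D array")
  if (length(angles) < 1L) stop("'angles' must not be empty")
  if (is.null(width)) width <- dim(volume)[2]
  proj <- project_volume_cpp(volume, as.numeric(angles) * pi / 180,
                             as.integer(width))
  tilt_series(proj, angles)
}

#' Inject a controlled rotation-axis misalignment
#'
#' Applies the same in-plane transform to every projection: rotation by
#' `theta` about the image centre followed by translation `delta` along the
#' detector x direction, emulating a fixed detector/stage misalignment.
#' With this injection the effective mirror transform between the 0 and 180
#' degree frames is exactly [mirror_transform()] at the injected parameters,
#' so the estimator's target equals the injected values.
#'
#' @param series A [tilt_series()].
#' @param params An [axis_params()] object.
#' @param interp Interpolation passed to [apply_planar_transform()].
#' @return The misaligned [tilt_series()].
#' @export
inject_misalignment <- function(series, params, interp = "bilinear") {
  p <- axis_params(params$theta, params$delta)
  if (p$theta == 0 && p$delta == 0) return(series)
  fwd <- planar_transform(.trans3(p$delta) %*% .rot3(p$theta * pi / 180))
  out <- series$projections
  for (i in seq_along(series$angles))
    out[, , i] <- apply_planar_transform(series$projections[, , i], fwd,
                                         interp = interp)
  tilt_series(out, series$angles)
}
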