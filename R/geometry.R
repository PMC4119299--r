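#' Rotation-axis misalignment parameters
#'
#' Bundles the two parameters of the simplified misalignment model: the
#' in-plane flip angle of the rotation axis relative to the detector centre
#' line, and the lateral offset of the axis from that line. Axial and
#' beam-direction offsets of the stage are assumed negligible and have no
#' representation here.
#'
#' @param theta In-plane flip angle in degrees. The method is a small-angle
#'   one; values with `|theta| >= 45` are rejected.
#' @param delta Offset of the rotation axis from the projection centre line
#'   along the detector x direction, in pixels. Must be finite. Callers that
#'   know the projection width additionally require `|delta| < width/4`.
#' @return An object of class `"axis_params"`: a named list with elements
#'   `theta` (degrees) and `delta` (pixels).
#' @examples
#' axis_params(theta = -5, delta = 2)
#' @export
axis_params <- function(theta = 0, delta = 0) {
  if (inherits(theta, "axis_params")) return(theta)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    stop("'theta' must be a single finite number (degrees)")
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta))
    stop("'delta' must be a single finite number (pixels)")
  if (abs(theta) >= 45)
    stop("|theta| must be below 45 degrees (small-angle model)")
  structure(list(theta = as.numeric(theta), delta = as.numeric(delta)),
            class = "axis_params")
}

#' @export
print.axis_params <- function(x, ...) {
  cat(sprintf("axis parameters: theta = %.4f deg, delta = %.4f px\n",
              x$theta, x$delta))
  invisible(x)
}

#' Planar homogeneous transform
#'
#' A 3x3 homogeneous matrix acting on continuous projection-plane coordinates
#' `(x, y, 1)`, with x along detector columns and y along rows, origin at the
#' image centre. The bottom row must be exactly `(0, 0, 1)` and the linear
#' 2x2 block invertible.
#'
#' @param matrix A 3x3 numeric matrix.
#' @return An object of class `"planar_transform"` wrapping the matrix.
#' @export
planar_transform <- function(matrix) {
  if (inherits(matrix, "planar_transform")) return(matrix)
  m <- as.matrix(matrix)
  if (!is.numeric(m) || !all(dim(m) == c(3L, 3L)) || !all(is.finite(m)))
    stop("'matrix' must be a finite numeric 3x3 matrix")
  if (!isTRUE(all(m[3, ] == c(0, 0, 1))))
    stop("bottom row of a planar transform must be exactly (0, 0, 1)")
  d <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (abs(d) < 1e-12) stop("transform is not invertible")
  structure(list(matrix = m), class = "planar_transform")
}

#' @export
print.planar_transform <- function(x, ...) {
  cat("planar transform (homogeneous, centred coordinates):\n")
  print(unname(x$matrix))
  invisible(x)
}

# translation / rotation / reflection factors (degrees handled by callers)
.trans3 <- function(dx, dy = 0) {
  m <- diag(3); m[1, 3] <- dx; m[2, 3] <- dy; m
}
.rot3 <- function(rad) {
  c0 <- cos(rad); s0 <- sin(rad)
  matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3, 3)
}
.reflx3 <- function() diag(c(-1, 1, 1))

#' Mirror transform about the misaligned rotation axis
#'
#' The composite reflection that maps a point of the 0 degree projection onto
#' its mirror position in the 180 degree projection when the rotation axis is
#' flipped by `theta` and offset by `delta`: translate the axis onto the
#' origin, rotate it upright, reflect `x -> -x`, rotate back, translate back.
#' In closed form the linear block is
#' \eqn{R(\theta)\,\mathrm{diag}(-1,1)\,R(-\theta)} with translation
#' \eqn{(2\delta\cos^2\theta,\; 2\delta\sin\theta\cos\theta)}.
#' The result is an involution (a reflection about a line), so it is its own
#' inverse and the determinant of the linear block is -1.
#'
#' @param params An [axis_params()] object (or `theta` in degrees, see
#'   [axis_params()]).
#' @param delta Offset in pixels when `params` is given as a bare angle.
#' @return A [planar_transform()].
#' @examples
#' mirror_transform(axis_params(0, 2))  # x' = -x + 4
#' @export
mirror_transform <- function(params, delta = NULL) {
  p <- if (is.null(delta)) axis_params(params) else axis_params(params, delta)
  th <- p$theta * pi / 180
  c0 <- cos(th); s0 <- sin(th)
  m <- matrix(c(s0^2 - c0^2,    -2 * s0 * c0,     0,
                -2 * s0 * c0,   c0^2 - s0^2,      0,
                2 * p$delta * c0^2, 2 * p$delta * s0 * c0, 1), 3, 3)
  planar_transform(m)
}

#' Correction transform applied to the 180 degree projection
#'
#' The transform \eqn{T^{k-1}} of the iterative scheme: with the current
#' estimates \eqn{(\tilde\theta, \tilde\delta)} it rotates the 180 degree
#' frame by \eqn{-2\tilde\theta} and reflects it about the
#' \eqn{\tilde\delta}-offset axis, built from the factor product
#' `Trans(delta) . Reflect(x) . Rot(-2 theta) . Trans(-delta)`. This is the
#' same reflection as [mirror_transform()] evaluated at the estimates (the
#' two factorizations are algebraically identical); it is exposed separately
#' because it is the object the estimator iterates with.
#'
#' @inheritParams mirror_transform
#' @return A [planar_transform()].
#' @export
correction_transform <- function(params, delta = NULL) {
  p <- if (is.null(delta)) axis_params(params) else axis_params(params, delta)
  th <- p$theta * pi / 180
  m <- .trans3(p$delta) %*% .reflx3() %*% .rot3(-2 * th) %*% .trans3(-p$delta)
  m[3, ] <- c(0, 0, 1)  # exact bottom row despite fp products
  planar_transform(m)
}

#' Small-angle mirror map
#'
#' First-order (in the flip angle) approximation of [mirror_transform()]:
#' \deqn{x' = -x + 2(\delta - \theta y), \quad y' = y + 2(\delta - x)\theta}
#' with the angle in radians inside the formula. Accurate to second order in
#' the angle; intended for `|theta|` up to about 10 degrees.
#'
#' @param params An [axis_params()] object.
#' @param x,y Coordinates (pixels, centred); vectors are recycled together.
#' @return A list with components `x` and `y`, the mirrored coordinates.
#' @export
small_angle_mirror <- function(params, x, y) {
  p <- axis_params(params$theta, params$delta)
  th <- p$theta * pi / 180
  list(x = -x + 2 * (p$delta - th * y),
       y = y + 2 * (p$delta - x) * th)
}

#' Resample an image through a planar transform
#'
#' Output-driven resampling: each output pixel is sampled from the input at
#' the inverse-mapped continuous coordinate, so the result `out` satisfies
#' `out(p) = img(T^{-1} p)` in centred coordinates. Samples falling outside
#' the input grid are filled with 0 (projections are background-subtracted
#' upstream). At integer offsets the bilinear weights degenerate to 1 and the
#' resampling is exact.
#'
#' @param image A numeric matrix (rows = detector y, columns = detector x).
#' @param transform A [planar_transform()] (the forward map).
#' @param interp Interpolation: `"bilinear"` (default) or `"bicubic"`
#'   (Catmull-Rom).
#' @return A numeric matrix of the same shape.
#' @export
apply_planar_transform <- function(image, transform,
                                   interp = c("bilinear", "bicubic")) {
  interp <- match.arg(interp)
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix")
  if (!all(is.finite(image))) stop("'image' must be finite-valued")
  tr <- planar_transform(transform)
  ainv <- solve(tr$matrix)
  warp_affine_cpp(image, ainv, if (interp == "bicubic") 1L else 0L)
}
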