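#' Ellipsoid table of the modified 3D Shepp-Logan phantom
#'
#' The widely used high-contrast ("modified") variant of the ten-ellipsoid
#' 3D Shepp-Logan head phantom: outer shell intensity 1.0, inner shell -0.8,
#' and low-contrast internal features at +/-0.1/-0.2, on normalized
#' coordinates in \eqn{[-1, 1]^3}. `phi` is the in-plane rotation of each
#' ellipsoid about the z axis.
#'
#' @return A data frame with one row per ellipsoid and columns `a`, `b`, `c`
#'   (semi-axes), `x0`, `y0`, `z0` (centre), `phi` (degrees) and `A`
#'   (additive intensity).
#' @export
shepp_logan_ellipsoids <- function() {
  data.frame(
    a   = c(0.6900, 0.6624, 0.1100, 0.1600, 0.2100,
            0.0460, 0.0460, 0.0460, 0.0230, 0.0230),
    b   = c(0.9200, 0.8740, 0.3100, 0.4100, 0.2500,
            0.0460, 0.0460, 0.0230, 0.0230, 0.0460),
    c   = c(0.8100, 0.7800, 0.2200, 0.2800, 0.4100,
            0.0500, 0.0500, 0.0500, 0.0200, 0.0200),
    x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0  = c(0, -0.0184, 0, 0, 0.35, 0.10, -0.10, -0.605, -0.606, -0.605),
    z0  = c(0, 0, 0, 0, -0.15, 0.25, 0.25, 0, 0, 0),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0),
    A   = c(1.0, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  )
}

#' Evaluate the modified 3D Shepp-Logan field at points
#'
#' Pointwise (no anti-aliasing) evaluation of the phantom: the sum of the
#' intensities of all ellipsoids containing each point.
#'
#' @param x,y,z Normalized coordinates in \eqn{[-1, 1]} (recycled together).
#' @param ellipsoids Ellipsoid table, by default [shepp_logan_ellipsoids()].
#' @return Numeric vector (or array, matching the input shape) of values.
#' @export
shepp_logan_value <- function(x, y, z, ellipsoids = shepp_logan_ellipsoids()) {
  v <- x * 0 + y * 0 + z * 0
  for (i in seq_len(nrow(ellipsoids))) {
    e <- ellipsoids[i, ]
    ph <- e$phi * pi / 180
    xr <- (x - e$x0) * cos(ph) + (y - e$y0) * sin(ph)
    yr <- -(x - e$x0) * sin(ph) + (y - e$y0) * cos(ph)
    zr <- z - e$z0
    inside <- (xr / e$a)^2 + (yr / e$b)^2 + (zr / e$c)^2 <= 1
    v <- v + e$A * inside
  }
  v
}

#' Sample the modified 3D Shepp-Logan phantom on a cubic grid
#'
#' Samples [shepp_logan_value()] on an `n^3` grid spanning
#' \eqn{[-1, 1]^3} (grid `seq(-1, 1, length.out = n)` per axis).
#' Deterministic and purely pointwise, so coincident sample points of nested
#' grids agree exactly.
#'
#' The returned array is indexed `[axial, x, y]`: the first index runs along
#' the rotation axis (the phantom's z), so `vol[a, , ]` is the in-plane slice
#' reconstructed by CT at axial position `a`.
#'
#' @param n Side length in voxels, at least 16.
#' @return A numeric `n x n x n` array, nonnegative up to floating
#'   round-off.
#' @examples
#' v <- shepp_logan_3d(32)
#' range(v)
#' @export
shepp_logan_3d <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 16 || n != round(n))
    stop("'n' must be a single integer >= 16")
  n <- as.integer(n)
  g <- seq(-1, 1, length.out = n)
  ell <- shepp_logan_ellipsoids()
  vol <- array(0, c(n, n, n))
  zm <- matrix(g, n, n)              # axial coordinate, varies along rows
  xm <- matrix(g, n, n, byrow = TRUE)  # in-plane x, varies along columns
  for (j in seq_len(n))  # in-plane y
    vol[, , j] <- shepp_logan_value(xm, g[j], zm, ell)
  vol
}

#' Indices of the four middle axial slices
#'
#' The four central slices used for quantitative evaluation: in 0-based
#' terms `{n/2-2, n/2-1, n/2, n/2+1}`.
#'
#' @param n Number of axial slices (detector rows).
#' @return Integer vector of four 1-based slice indices.
#' @export
middle_slices <- function(n) {
  as.integer(n %/% 2 + c(-1L, 0L, 1L, 2L))
}
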