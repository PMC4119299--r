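#' Correct a tilt series for the estimated misalignment
#'
#' Applies the inverse of the misalignment to every projection: translate by
#' `-delta` along x, then rotate by `-theta` about the image centre — the
#' exact inverse of the injection order (rotate, then translate).
#'
#' @param series A [tilt_series()].
#' @param params An [axis_params()], typically `coef` of an
#'   [estimate_axis()] fit (pass `axis_params(theta, delta)`).
#' @param interp Interpolation passed to [apply_planar_transform()].
#' @return The corrected [tilt_series()].
#' @export
correct_series <- function(series, params, interp = "bilinear") {
  p <- axis_params(params$theta, params$delta)
  if (p$theta == 0 && p$delta == 0) return(series)
  fwd <- planar_transform(.rot3(-p$theta * pi / 180) %*% .trans3(-p$delta))
  out <- series$projections
  for (i in seq_along(series$angles))
    out[, , i] <- apply_planar_transform(series$projections[, , i], fwd,
                                         interp = interp)
  tilt_series(out, series$angles)
}

#' Build sinograms from a tilt series
#'
#' Lossless re-indexing: the sinogram for detector row `r` collects row `r`
#' of every projection in angle order.
#'
#' @param series A [tilt_series()].
#' @param rows Detector rows to extract (default: all).
#' @return A list of `"sinogram"` objects, each a list with `values`
#'   (`n_angles x width` matrix), `angles` (degrees) and `row`.
#' @export
build_sinograms <- function(series, rows = NULL) {
  stopifnot(inherits(series, "tilt_series"))
  d <- dim(series$projections)
  if (is.null(rows)) rows <- seq_len(d[1])
  if (any(rows < 1 | rows > d[1])) stop("rows out of range")
  lapply(rows, function(r) {
    structure(list(values = t(series$projections[r, , ]),
                   angles = series$angles, row = r),
              class = "sinogram")
  })
}

#' Rebuild a tilt series from a full set of sinograms
#'
#' Inverse of [build_sinograms()] when called with all rows.
#'
#' @param sinos List of sinograms covering rows `1..H` of the original
#'   series.
#' @return A [tilt_series()].
#' @export
sinograms_to_series <- function(sinos) {
  rows <- vapply(sinos, `[[`, 0L, "row")
  o <- order(rows)
  sinos <- sinos[o]
  angles <- sinos[[1]]$angles
  w <- ncol(sinos[[1]]$values)
  proj <- array(0, c(length(sinos), w, length(angles)))
  for (i in seq_along(sinos)) proj[i, , ] <- t(sinos[[i]]$values)
  tilt_series(proj, angles)
}

# Discrete ramp (Ram-Lak) filter, built in the spatial domain so the DC
# component is handled correctly, then transformed: h(0) = 1/4,
# h(k) = -1/(pi k)^2 for odd k, 0 for even k (unit detector sampling).
.ramp_filter <- function(m) {
  h <- numeric(m)
  h[1] <- 0.25
  k <- seq_len(m - 1)
  kc <- pmin(k, m - k)  # circular distance
  odd <- kc %% 2 == 1
  h[1 + which(odd)] <- -1 / (pi * kc[odd])^2
  2 * Re(stats::fft(h))
}

#' Filtered back-projection of one sinogram
#'
#' Standard parallel-beam FBP: each projection row is convolved with the
#' discrete ramp (Ram-Lak) filter via FFT (zero-padded to the next power of
#' two of at least twice the detector width), then back-projected with
#' linear detector interpolation and scaled by `pi / (2 n_angles)`. The
#' output is square with side equal to the detector width and masked to the
#' inscribed circle.
#'
#' @param sino A `"sinogram"` from [build_sinograms()], or an
#'   `n_angles x width` matrix (then `angles` is required).
#' @param angles Tilt angles in degrees when `sino` is a bare matrix.
#' @param mask Zero out pixels outside the inscribed circle (default TRUE).
#' @return A `width x width` slice image.
#' @export
fbp_reconstruct <- function(sino, angles = NULL, mask = TRUE) {
  if (inherits(sino, "sinogram")) {
    angles <- sino$angles
    sino <- sino$values
  }
  stopifnot(is.matrix(sino))
  if (is.null(angles) || length(angles) != nrow(sino))
    stop("need one tilt angle per sinogram row")
  if (length(angles) < 2L || diff(range(angles)) <= 0 ||
      max(angles) - min(angles) > 180)
    stop("degenerate angle coverage: need >= 2 angles spanning (0, 180]")
  w <- ncol(sino)
  m <- 2^ceiling(log2(max(64, 2 * w)))
  filt <- .ramp_filter(m)
  padded <- matrix(0, m, nrow(sino))
  padded[seq_len(w), ] <- t(sino)
  fs <- Re(stats::mvfft(stats::mvfft(padded) * filt, inverse = TRUE)) / m
  fsino <- t(fs[seq_len(w), , drop = FALSE])
  rec <- backproject_cpp(fsino, angles * pi / 180, as.integer(w)) *
    pi / (2 * length(angles))
  if (mask) {
    cc <- (w - 1) / 2
    g <- seq_len(w) - 1 - cc
    rec[outer(g^2, g^2, `+`) > cc^2] <- 0
  }
  rec
}

#' Reconstruct a set of axial slices from a tilt series
#'
#' Convenience wrapper: [build_sinograms()] for the requested rows followed
#' by [fbp_reconstruct()] on each.
#'
#' @param series A [tilt_series()].
#' @param rows Detector rows (axial slice indices); default the four middle
#'   slices.
#' @param mask Passed to [fbp_reconstruct()].
#' @return A `width x width x length(rows)` array with attribute `"rows"`.
#' @export
reconstruct_slices <- function(series, rows = NULL, mask = TRUE) {
  d <- dim(series$projections)
  if (is.null(rows)) rows <- middle_slices(d[1])
  sinos <- build_sinograms(series, rows)
  out <- array(0, c(d[2], d[2], length(rows)))
  for (i in seq_along(sinos))
    out[, , i] <- fbp_reconstruct(sinos[[i]], mask = mask)
  attr(out, "rows") <- rows
  out
}
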