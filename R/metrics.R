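# Separable "valid"-mode convolution with a symmetric 1D kernel, via banded
# matrix products; output shrinks by (length(k) - 1) in each dimension.
.sep_filter_valid <- function(m, k) {
  ks <- length(k)
  band <- function(n) {
    nb <- n - ks + 1L
    b <- matrix(0, nb, n)
    for (i in seq_len(nb)) b[i, i:(i + ks - 1L)] <- k
    b
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

.gaussian_kernel <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Mean structural similarity index (mSSIM)
#'
#' Local SSIM computed over a sliding Gaussian window,
#' \deqn{\mathrm{SSIM} = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with \eqn{C_1 = (K_1 L)^2}, \eqn{C_2 = (K_2 L)^2}, averaged over all
#' window positions (valid region). By default both images are jointly
#' rescaled to `[0, 1]` by the min/max of the reference `y`, and `L = 1`;
#' pass `dynamic_range` to skip the rescaling and use the images as given.
#'
#' @param x Image under test (numeric matrix).
#' @param y Reference image, same shape.
#' @param window_size Side of the Gaussian window (odd; default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param K1,K2 Stabilization fractions (defaults 0.01, 0.03).
#' @param dynamic_range Value range `L`; `NULL` (default) normalizes both
#'   images by the reference min/max and uses `L = 1`.
#' @return The mean SSIM, a scalar in `(-1, 1]`, exactly 1 when `x == y`.
#' @export
mean_ssim <- function(x, y, window_size = 11L, sigma = 1.5,
                      K1 = 0.01, K2 = 0.03, dynamic_range = NULL) {
  stopifnot(is.matrix(x), is.matrix(y))
  if (!identical(dim(x), dim(y))) stop("image shapes differ")
  if (K1 <= 0 || K2 <= 0) stop("K1 and K2 must be positive")
  if (window_size > min(dim(x))) stop("window does not fit in image")
  if (is.null(dynamic_range)) {
    rng <- range(y)
    sc <- if (diff(rng) > 0) diff(rng) else 1
    x <- (x - rng[1]) / sc
    y <- (y - rng[1]) / sc
    L <- 1
  } else {
    L <- dynamic_range
  }
  c1 <- (K1 * L)^2
  c2 <- (K2 * L)^2
  k <- .gaussian_kernel(window_size, sigma)
  mu_x <- .sep_filter_valid(x, k)
  mu_y <- .sep_filter_valid(y, k)
  sxx <- .sep_filter_valid(x * x, k) - mu_x^2
  syy <- .sep_filter_valid(y * y, k) - mu_y^2
  sxy <- .sep_filter_valid(x * y, k) - mu_x * mu_y
  ssim <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(ssim)
}

.entropy <- function(p, base) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Mutual information between two images
#'
#' \eqn{MI(X, Y) = H(X) + H(Y) - H(X, Y)} with Shannon entropies computed
#' from an equal-width joint histogram over the combined min/max of both
#' images (so `mutual_information(x, x)` equals `H(x)` under the same
#' binning). Zero-probability bins contribute nothing (`0 log 0 = 0`).
#'
#' @param x,y Images of identical shape.
#' @param bins Number of histogram bins per axis (default 256).
#' @param base Logarithm base (default 2: bits).
#' @return The mutual information (nonnegative up to floating error);
#'   0 for constant images.
#' @export
mutual_information <- function(x, y, bins = 256L, base = 2) {
  stopifnot(is.matrix(x), is.matrix(y))
  if (!identical(dim(x), dim(y))) stop("image shapes differ")
  if (bins < 2L) stop("'bins' must be at least 2")
  lo <- min(x, y); hi <- max(x, y)
  if (hi <= lo) return(0)
  ix <- pmin(bins, floor((as.vector(x) - lo) / (hi - lo) * bins) + 1L)
  iy <- pmin(bins, floor((as.vector(y) - lo) / (hi - lo) * bins) + 1L)
  joint <- tabulate((ix - 1L) * bins + iy, nbins = bins * bins)
  pj <- joint / length(ix)
  px <- tabulate(ix, nbins = bins) / length(ix)
  py <- tabulate(iy, nbins = bins) / length(iy)
  .entropy(px, base) + .entropy(py, base) - .entropy(pj, base)
}

#' Evaluate reconstructed slices against references
#'
#' Per-slice [mean_ssim()] and [mutual_information()] between two slice
#' stacks.
#'
#' @param x Stack under test (`W x W x k` array).
#' @param reference Reference stack of identical shape.
#' @param bins,base Passed to [mutual_information()].
#' @param ... Passed to [mean_ssim()].
#' @return A data frame with columns `slice`, `mssim`, `mi`.
#' @export
evaluate_slices <- function(x, reference, bins = 256L, base = 2, ...) {
  stopifnot(is.array(x), is.array(reference),
            identical(dim(x), dim(reference)))
  k <- dim(x)[3]
  rows <- attr(x, "rows")
  data.frame(
    slice = if (is.null(rows)) seq_len(k) else rows,
    mssim = vapply(seq_len(k), function(i)
      mean_ssim(x[, , i], reference[, , i], ...), 0),
    mi = vapply(seq_len(k), function(i)
      mutual_information(x[, , i], reference[, , i], bins = bins,
                         base = base), 0))
}
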