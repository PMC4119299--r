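# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# phantom volumes and 0/180 projection pairs
phantom_vol <- function(n) {
  fixture(paste0("vol", n), function() shepp_logan_3d(n))
}

phantom_pair <- function(n) {
  fixture(paste0("pair", n), function()
    simulate_tilt_series(phantom_vol(n), c(0, 180)))
}

# deterministic smooth test image: sum of Gaussian blobs, zero margins
smooth_image <- function(n = 64, margin = 12, seed = 7, k = 6) {
  set.seed(seed)
  img <- matrix(0, n, n)
  ctr <- (n + 1) / 2
  for (i in seq_len(k)) {
    cx <- runif(1, -n / 4, n / 4)
    cy <- runif(1, -n / 4, n / 4)
    s <- runif(1, 3, 9)
    img <- img + outer(seq_len(n), seq_len(n), function(r, c)
      exp(-((r - ctr - cy)^2 + (c - ctr - cx)^2) / (2 * s^2)))
  }
  if (margin > 0) {
    img[c(seq_len(margin), seq(n - margin + 1, n)), ] <- 0
    img[, c(seq_len(margin), seq(n - margin + 1, n))] <- 0
  }
  img
}

# normalized correlation between two images over an interior window
interior_cor <- function(a, b, border = 10) {
  r <- seq(border + 1, nrow(a) - border)
  c <- seq(border + 1, ncol(a) - border)
  stats::cor(as.vector(a[r, c]), as.vector(b[r, c]))
}

# brute-force row-shift oracle: exhaustive ZNCC argmax over all integer lags
brute_force_row_lag <- function(u, v, max_lag) {
  w <- length(u)
  lags <- seq.int(-max_lag, max_lag)
  z <- vapply(lags, function(t0) {
    j <- max(1, 1 - t0):min(w, w - t0)
    a <- u[j + t0]; b <- v[j]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, 0)
  lags[which.max(z)]
}

# entropy of a binned image, for the MI(X, X) = H(X) identity
binned_entropy <- function(x, bins, base = 2) {
  lo <- min(x); hi <- max(x)
  ix <- pmin(bins, floor((as.vector(x) - lo) / (hi - lo) * bins) + 1L)
  p <- tabulate(ix, bins) / length(ix)
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}
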