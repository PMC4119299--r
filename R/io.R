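#' Write a tilt series to a multi-page TIFF with a JSON sidecar
#'
#' Projections are written as a 32-bit multi-page TIFF. Values are scaled to
#' `[0, 1]` for storage (relative round-trip error about 2e-10) and the
#' original range is recorded, together with the tilt angles, in a JSON
#' sidecar `<path>.json`.
#'
#' @param series A [tilt_series()].
#' @param path Output TIFF path (e.g. `"series.tif"`).
#' @return `path`, invisibly.
#' @export
write_tilt_series <- function(series, path) {
  stopifnot(inherits(series, "tilt_series"))
  rng <- range(series$projections)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_along(series$angles), function(i)
    (series$projections[, , i] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(angles = series$angles, vmin = rng[1], vmax = rng[2],
         height = dim(series$projections)[1],
         width = dim(series$projections)[2]),
    paste0(path, ".json"), digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a tilt series written by [write_tilt_series()]
#'
#' @param path TIFF path; the sidecar `<path>.json` must sit next to it.
#' @return A [tilt_series()].
#' @export
read_tilt_series <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- meta$vmax - meta$vmin
  if (scale <= 0) scale <- 1
  pages <- lapply(pages, function(m) m * scale + meta$vmin)
  tilt_series(pages, meta$angles)
}

#' Write a stack of slices (or any image stack) to multi-page TIFF
#'
#' Same storage scheme as [write_tilt_series()] but for a plain image stack;
#' the sidecar records the value range and an optional index vector.
#'
#' @param stack `H x W x k` numeric array.
#' @param path Output TIFF path.
#' @param index Optional numeric labels for the pages (e.g. slice rows).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, index = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  rng <- range(stack)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(stack)[3]), function(i)
    (stack[, , i] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(vmin = rng[1], vmax = rng[2],
         index = if (is.null(index)) seq_len(dim(stack)[3]) else index),
    paste0(path, ".json"), digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path with sidecar `<path>.json`.
#' @return An `H x W x k` array with attribute `"index"`.
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- meta$vmax - meta$vmin
  if (scale <= 0) scale <- 1
  out <- array(unlist(lapply(pages, function(m) m * scale + meta$vmin)),
               c(dim(pages[[1]]), length(pages)))
  attr(out, "index") <- meta$index
  out
}
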