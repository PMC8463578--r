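# Poisson rate coding: static images -> binary spike rasters.

#' Validate and coerce an image tensor
#'
#' Images are arrays `(channels, rows, cols)` with intensities in `[0, 255]`.
#' A plain matrix is treated as a single-channel image.
#'
#' @param pixels Matrix `(rows, cols)` or array `(channels, rows, cols)`.
#' @return A validated 3-d array of class `image_tensor`.
#' @export
image_tensor <- function(pixels) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, c(1L, nrow(pixels), ncol(pixels)))
  }
  if (length(dim(pixels)) != 3L) stopf("image must be (channels, rows, cols)")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255)) {
    stopf("pixel intensities must lie in [0, 255]")
  }
  structure(pixels, class = "image_tensor")
}

#' Poisson rate coding of an image
#'
#' Independently for every pixel and time-step, a spike is emitted with
#' probability `p / 255` where `p` is the pixel intensity, so the expected
#' spike count over `T` steps is proportional to intensity. Sampling is
#' `spike <- runif(1) < p / 255`; intensity 0 never spikes and intensity 255
#' spikes at every step.
#'
#' @param image An [image_tensor()] (or matrix/array coercible to one).
#' @param timesteps Number of steps `T >= 1`.
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream. Same seed, same raster.
#' @return Binary spike raster array `(T, channels, rows, cols)`.
#' @export
poisson_encode <- function(image, timesteps, seed = NULL) {
  image <- image_tensor(unclass(image))
  timesteps <- as.integer(timesteps)
  if (timesteps < 1L) stopf("timesteps must be >= 1")
  d <- dim(image)
  p <- as.numeric(image) / 255
  with_seed(seed, {
    u <- stats::runif(timesteps * length(p))
    # u laid out (T fastest) so each pixel sees T i.i.d. draws
    raster <- array((u < rep(p, each = timesteps)) * 1, c(timesteps, d))
    raster
  })
}

# Batched encoding: images (C, H, W, B) -> raster (T, C, H, W, B), drawn from
# the current RNG stream (callers seed the surrounding computation).
poisson_encode_batch <- function(images, timesteps) {
  d <- dim(images)
  p <- as.numeric(images) / 255
  u <- stats::runif(timesteps * length(p))
  array((u < rep(p, each = timesteps)) * 1, c(timesteps, d))
}
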