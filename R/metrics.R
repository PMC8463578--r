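# Quantitative evaluation of heatmap sequences.

as_heatmap_array <- function(seq) {
  x <- unclass(seq)
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  if (length(dim(x)) != 3L || dim(x)[1] == 0) stopf("expected a (T, H, W) heatmap sequence")
  x
}

#' Localization error against a reference map
#'
#' Per-time-step binary cross-entropy between the normalized heatmap sequence
#' `M_t` and a reference Grad-CAM map `G` (both in `[0, 1]`), minimized over
#' time. The reference is resized to the sequence's resolution (preserving
#' each layer's native granularity), and `M` is clamped to
#' `[delta, 1 - delta]` before the logarithms.
#'
#' @param sam_seq A normalized [heatmap_sequence()].
#' @param reference 2-D reference map `G` in `[0, 1]`.
#' @param delta Clamp constant guarding `log(0)`.
#' @return List with `error` (the min over time), `t` (the argmin step), and
#'   the per-step `trace`.
#' @export
localization_error <- function(sam_seq, reference, delta = 1e-6) {
  m <- as_heatmap_array(sam_seq)
  if (any(m < 0) || any(m > 1)) stopf("heatmap sequence must be normalized to [0, 1]")
  if (any(reference < 0) || any(reference > 1)) stopf("reference must be in [0, 1]")
  G <- resize_heatmap(as.matrix(reference), dim(m)[2], dim(m)[3])
  npix <- length(G)
  trace <- vapply(seq_len(dim(m)[1]), function(t) {
    mt <- clamp(matrix(m[t, , ], dim(m)[2], dim(m)[3]), delta, 1 - delta)
    -sum(G * log(mt) + (1 - G) * log(1 - mt)) / npix
  }, numeric(1))
  list(error = min(trace), t = which.min(trace), trace = trace)
}

#' Maximum-over-time pixel-wise heatmap variance
#'
#' Population variance of the pixel values of each per-time-step map; the
#' maximum across time-steps is returned (low values indicate the
#' non-discriminative "heatmap smoothing effect").
#'
#' @param seq A [heatmap_sequence()] (normalized).
#' @return Scalar maximum variance.
#' @export
heatmap_variance <- function(seq) {
  m <- as_heatmap_array(seq)
  v <- vapply(seq_len(dim(m)[1]), function(t) {
    x <- m[t, , ]
    mean((x - mean(x))^2)
  }, numeric(1))
  max(v)
}

#' Normalized L1 distance between heatmap sequences
#'
#' Mean absolute pixel difference per time-step, maximized over time. Both
#' sequences must be normalized to `[0, 1]` and share shape and length (the
#' single-map ANN case is `T = 1`). The result lies in `[0, 1]`.
#'
#' @param seq_a,seq_b Normalized heatmap sequences (or single 2-D maps).
#' @return Scalar maximum-over-time mean absolute difference.
#' @export
heatmap_l1 <- function(seq_a, seq_b) {
  a <- as_heatmap_array(seq_a)
  b <- as_heatmap_array(seq_b)
  if (!identical(dim(a), dim(b))) stopf("heatmap sequences must share shape and T")
  v <- vapply(seq_len(dim(a)[1]), function(t) mean(abs(a[t, , ] - b[t, , ])),
              numeric(1))
  max(v)
}

#' Fraction of heatmap mass inside a ground-truth mask
#'
#' For synthetic data with a known discriminative region, measures how much
#' of each map's mass falls inside the binary mask and returns the best
#' fraction over time. Maps are resized to the mask's resolution. Defined as
#' 0 when every map is all-zero.
#'
#' @param seq A [heatmap_sequence()].
#' @param mask Binary matrix marking the discriminative region.
#' @return Scalar in `[0, 1]`.
#' @export
mask_localization_score <- function(seq, mask) {
  mask <- as.matrix(mask)
  assert_binary(mask, "mask")
  m <- as_heatmap_array(seq)
  best <- 0
  for (t in seq_len(dim(m)[1])) {
    mt <- resize_heatmap(matrix(m[t, , ], dim(m)[2], dim(m)[3]),
                         nrow(mask), ncol(mask))
    tot <- sum(mt)
    if (tot > 0) best <- max(best, sum(mt * mask) / tot)
  }
  best
}
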