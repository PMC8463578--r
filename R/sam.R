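# Spike activation maps (SAM).
#
# Every neuron keeps a neuronal contribution score (NCS): the sum, over its
# strictly-previous firing times t', of an exponential inter-spike-interval
# kernel exp(-gamma * |t - t'|). The per-time-step heatmap is the channel sum
# of NCS x current spike activity. The whole computation is a single forward
# sweep over the recorded raster: no labels, no gradients.

#' Temporal spike contribution score kernel
#'
#' `exp(-gamma * |t - t_prev|)`: the contribution of a past spike at `t_prev`
#' to the neuronal state at `t`. `gamma` controls the steepness; `gamma = 0`
#' weights all past spikes equally.
#'
#' @param t Current time-step.
#' @param t_prev Previous firing time, `t_prev <= t`.
#' @param gamma Kernel steepness, `gamma >= 0`.
#' @return Kernel value in `(0, 1]`.
#' @export
tscs_kernel <- function(t, t_prev, gamma) {
  if (!is.numeric(gamma) || anyNA(gamma) || any(gamma < 0) || any(!is.finite(gamma))) {
    stopf("gamma must be finite and >= 0")
  }
  if (any(t_prev > t)) stopf("t_prev must not exceed t")
  exp(-gamma * abs(t - t_prev))
}

#' One incremental NCS update
#'
#' Advances the running neuronal contribution scores by one step:
#' `N_t = exp(-gamma) * (N_{t-1} + s_{t-1})`, which is algebraically identical
#' to summing `tscs_kernel(t, t')` over all strictly-previous spike times.
#' Scores at `t = 1` are all zero (no previous spikes).
#'
#' @param prev_scores NCS field at `t - 1` (array or scalar).
#' @param prev_spikes Binary spikes at `t - 1`, same shape.
#' @param gamma Kernel steepness, `gamma >= 0`.
#' @return NCS field at `t`.
#' @export
ncs_step <- function(prev_scores, prev_spikes, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma < 0) {
    stopf("gamma must be a single value >= 0")
  }
  if (length(prev_scores) != length(prev_spikes)) {
    stopf("prev_scores and prev_spikes shapes do not match")
  }
  assert_binary(prev_spikes, "prev_spikes")
  exp(-gamma) * (prev_scores + prev_spikes)
}

#' Compute the spike activation map sequence
#'
#' For a recorded spike raster of one layer, computes the per-time-step
#' heatmap `M_t = sum_k N_{k,t} * S_{k,t}` where `N` is the NCS field and `S`
#' the binary spike activity. Requires no class label and no backward pass.
#'
#' @param raster Binary spike raster `(T, K, H, W)`.
#' @param gamma Kernel steepness (default 0.2, mid-range between the flat
#'   kernel and a one-step memory).
#' @return A `heatmap_sequence`: array `(T, H, W)` of non-negative maps.
#' @export
compute_sam <- function(raster, gamma = 0.2) {
  d <- dim(raster)
  if (is.null(d) || length(d) != 4L || any(d == 0)) {
    stopf("raster must be a non-empty (T, K, H, W) array")
  }
  assert_binary(raster, "raster")
  T <- d[1]
  maps <- array(0, c(T, d[3], d[4]))
  ncs <- array(0, d[-1])
  decay <- exp(-gamma)
  for (t in seq_len(T)) {
    s_t <- array(raster[t, , , , drop = FALSE], d[-1])
    contrib <- ncs * s_t
    maps[t, , ] <- array(colSums(matrix(contrib, nrow = d[2])), c(1L, d[3], d[4]))
    ncs <- decay * (ncs + s_t)
  }
  heatmap_sequence(maps)
}

#' Heatmap sequence container
#'
#' @param maps Array `(T, H, W)` of non-negative per-time-step maps.
#' @return The array with class `heatmap_sequence`.
#' @export
heatmap_sequence <- function(maps) {
  if (length(dim(maps)) != 3L) stopf("heatmap sequence must be (T, H, W)")
  if (any(maps < 0)) stopf("heatmaps must be non-negative")
  structure(maps, class = "heatmap_sequence")
}

#' Normalize a heatmap sequence to [0, 1]
#'
#' By default divides every map by the single global maximum across all
#' time-steps of the sample, which keeps the temporal evolution comparable
#' across steps. `per_timestep = TRUE` normalizes each map by its own maximum
#' instead. An all-zero input maps to all zeros.
#'
#' @param seq A [heatmap_sequence()] (or `(T, H, W)` array).
#' @param per_timestep Normalize each time-step independently.
#' @return Normalized `heatmap_sequence` with values in `[0, 1]`.
#' @export
normalize_heatmaps <- function(seq, per_timestep = FALSE) {
  x <- unclass(seq)
  assert_finite(x, "heatmaps")
  if (any(x < 0)) stopf("heatmaps must be non-negative")
  if (per_timestep) {
    for (t in seq_len(dim(x)[1])) {
      m <- max(x[t, , ])
      if (m > 0) x[t, , ] <- x[t, , ] / m
    }
  } else {
    m <- max(x)
    if (m > 0) x <- x / m
  }
  heatmap_sequence(x)
}

#' Bilinear heatmap resizing
#'
#' Corner-aligned bilinear interpolation used to reconcile layer-resolution
#' maps with image- or mask-resolution references. Constant maps stay
#' constant and outputs stay within the input's range.
#'
#' @param map 2-D numeric matrix.
#' @param target_rows,target_cols Output size, each `>= 1`.
#' @return A `target_rows x target_cols` matrix.
#' @export
resize_heatmap <- function(map, target_rows, target_cols) {
  map <- as.matrix(map)
  target_rows <- as.integer(target_rows)
  target_cols <- as.integer(target_cols)
  if (target_rows < 1L || target_cols < 1L) stopf("target sizes must be >= 1")
  h <- nrow(map)
  w <- ncol(map)
  if (h == target_rows && w == target_cols) return(map)
  src_r <- if (target_rows == 1L) rep((h + 1) / 2, 1L) else 1 + (seq_len(target_rows) - 1) * (h - 1) / (target_rows - 1)
  src_c <- if (target_cols == 1L) rep((w + 1) / 2, 1L) else 1 + (seq_len(target_cols) - 1) * (w - 1) / (target_cols - 1)
  r0 <- clamp(floor(src_r), 1, h)
  c0 <- clamp(floor(src_c), 1, w)
  r1 <- pmin(r0 + 1, h)
  c1 <- pmin(c0 + 1, w)
  fr <- src_r - r0
  fc <- src_c - c0
  top <- map[r0, c0, drop = FALSE] * (1 - fc)[col(matrix(0, target_rows, target_cols))] +
    map[r0, c1, drop = FALSE] * fc[col(matrix(0, target_rows, target_cols))]
  bot <- map[r1, c0, drop = FALSE] * (1 - fc)[col(matrix(0, target_rows, target_cols))] +
    map[r1, c1, drop = FALSE] * fc[col(matrix(0, target_rows, target_cols))]
  top * (1 - fr) + bot * fr
}
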