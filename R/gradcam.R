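# Grad-CAM baselines: standard Grad-CAM on the reference ANN, and the
# SNN-crafted variant obtained by accumulating surrogate backward gradients
# over all time-steps. Both need the ground-truth class label, unlike SAM.

#' Triangular surrogate derivative of the spike function
#'
#' Piecewise-linear pseudo-derivative used wherever the non-differentiable
#' spike nonlinearity must be differentiated: peak 1 at `u = theta`, falling
#' linearly to 0 at `|u - theta| >= width`. The default width equals the
#' threshold (the common threshold-scaled choice).
#'
#' @param u Membrane potential(s).
#' @param theta Firing threshold.
#' @param width Half-width of the triangle, `> 0`.
#' @return Pseudo-derivative values in `[0, 1]`, same shape as `u`.
#' @export
surrogate_grad <- function(u, theta, width = theta) {
  if (!is.finite(theta)) {
    # accumulator layers never fire; the spike path carries no gradient
    return(u * 0)
  }
  if (!is.numeric(width) || width <= 0) stopf("surrogate width must be > 0")
  g <- 1 - abs(u - theta) / width
  g[g < 0] <- 0
  g
}

#' SNN-crafted Grad-CAM
#'
#' Runs a full forward simulation, backpropagates the target-class logit
#' through time with surrogate derivatives, and forms channel weights
#' `alpha_k = (1/N) * sum_{i,j,t} d y_c / d A_{k,ij,t}` with `N = T * H * W`
#' of the target layer. The per-time-step map is the ReLU of the
#' channel-weighted spike activity, `G_t = max(0, sum_k alpha_k * A_{k,t})`.
#'
#' @param config A [network_config()].
#' @param weights Trained network weights.
#' @param input_raster Binary spike raster `(T, C, H, W)`.
#' @param class_label Ground-truth class index (1-based).
#' @param target_layer Index of the recorded conv layer to explain.
#' @return A [heatmap_sequence()] `(T, H, W)` at the target layer's
#'   resolution, with the channel weights attached as attribute `"alpha"`.
#' @export
snn_gradcam <- function(config, weights, input_raster, class_label,
                        target_layer) {
  if (class_label < 1L || class_label > config$num_classes) {
    stopf("class_label must be in 1..%d", config$num_classes)
  }
  if (!(target_layer %in% lif_layer_indices(config)) ||
      config$layers[[target_layer]]$kind != "conv") {
    stopf("target_layer must be a conv LIF layer")
  }
  d <- dim(input_raster)
  if (length(d) != 4L) stopf("input raster must be (T, C, H, W)")
  raster <- array(input_raster, c(d, 1L))
  fwd <- snn_forward(config, weights, raster,
                     record_layers = target_layer, keep = TRUE)
  dlogits <- matrix(0, config$num_classes, 1L)
  dlogits[class_label, 1L] <- 1
  bwd <- snn_backward(config, weights, fwd, dlogits,
                      spike_grad_layer = target_layer)
  A <- fwd$records[[as.character(target_layer)]]   # (T, K, H, W, 1)
  g <- bwd$spike_grads                             # (T, K, H, W, 1)
  da <- dim(A)
  T <- da[1]; K <- da[2]; H <- da[3]; W <- da[4]
  nfac <- T * H * W
  gm <- matrix(aperm(array(g, da[1:4]), c(2, 1, 3, 4)), nrow = K)
  alpha <- rowSums(gm) / nfac
  maps <- array(0, c(T, H, W))
  for (t in seq_len(T)) {
    a_t <- matrix(array(A[t, , , , ], c(K, H * W)), nrow = K)
    maps[t, , ] <- array(relu(colSums(a_t * alpha)), c(1L, H, W))
  }
  structure(heatmap_sequence(maps), alpha = alpha)
}

#' Grad-CAM on the reference ANN
#'
#' Standard Grad-CAM: channel weights are the global-average-pooled gradients
#' of the class score with respect to the target layer's (post-ReLU)
#' activations; the map is the ReLU of the channel-weighted activation sum,
#' normalized to `[0, 1]`.
#'
#' @param config A [network_config()] describing the ANN topology (LIF
#'   parameters and BNTT flags are ignored; convs use ReLU).
#' @param weights ANN weights from [train_ann()].
#' @param image An [image_tensor()].
#' @param class_label Ground-truth class index (1-based).
#' @param target_layer Index of the conv layer to explain.
#' @return A single 2-D heatmap matrix in `[0, 1]`.
#' @export
ann_gradcam <- function(config, weights, image, class_label, target_layer) {
  if (class_label < 1L || class_label > config$num_classes) {
    stopf("class_label must be in 1..%d", config$num_classes)
  }
  image <- image_tensor(unclass(image))
  x <- array(as.numeric(image) / 255, c(dim(image), 1L))
  fwd <- ann_forward(config, weights, x, keep = TRUE,
                     record_layers = target_layer)
  dlogits <- matrix(0, config$num_classes, 1L)
  dlogits[class_label, 1L] <- 1
  bwd <- ann_backward(config, weights, fwd, dlogits,
                      act_grad_layer = target_layer)
  A <- fwd$records[[as.character(target_layer)]]  # (K, H, W, 1)
  g <- bwd$act_grad                               # same shape
  da <- dim(A)
  K <- da[1]; H <- da[2]; W <- da[3]
  alpha <- rowMeans(matrix(g, nrow = K))          # global average pooling
  map <- matrix(relu(colSums(matrix(A, nrow = K) * alpha)), H, W)
  m <- max(map)
  if (m > 0) map <- map / m
  map
}

#' Per-layer heatmap discriminativeness probe
#'
#' Computes, for one sample, the maximum-over-time pixel-wise heatmap
#' variance of SAM and of SNN-crafted Grad-CAM at each requested layer
#' (both normalized to `[0, 1]` first). Low variance indicates the
#' non-discriminative "heatmap smoothing" of surrogate-gradient maps.
#'
#' @param config A [network_config()].
#' @param weights Trained SNN weights.
#' @param input_raster Binary spike raster `(T, C, H, W)`.
#' @param class_label Ground-truth label (needed by Grad-CAM only).
#' @param layers Conv layer indices to probe.
#' @return A data frame with columns `method`, `layer`, `variance`.
#' @export
heatmap_smoothing_probe <- function(config, weights, input_raster, class_label,
                                    layers) {
  fw <- forward_network(config, weights, input_raster, record_layers = layers)
  rows <- lapply(layers, function(l) {
    sam <- normalize_heatmaps(compute_sam(fw$records[[as.character(l)]]))
    gc <- normalize_heatmaps(snn_gradcam(config, weights, input_raster,
                                         class_label, l))
    data.frame(method = c("sam", "snn_gradcam"), layer = l,
               variance = c(heatmap_variance(sam), heatmap_variance(gc)))
  })
  do.call(rbind, rows)
}

# --- reference ANN forward/backward ----------------------------------------

# ANN twin of the SNN engine: conv -> ReLU, average pooling, global average
# pooling, flatten, linear (+ ReLU if hidden). x: (C, H, W, B) in [0, 1].
ann_forward <- function(config, weights, x, keep = FALSE,
                        record_layers = integer()) {
  L <- length(config$layers)
  records <- list()
  cache <- if (keep) list(act = vector("list", L), xin = vector("list", L),
                          indim = vector("list", L), P = vector("list", L)) else NULL
  for (l in seq_len(L)) {
    spec <- config$layers[[l]]
    wl <- weights[[l]]
    if (spec$kind == "conv") {
      cf <- conv2d_forward(x, wl$W, spec$kernel, spec$kernel)
      x <- relu(cf$out)
      if (keep) {
        cache$P[[l]] <- cf$P
        cache$indim[[l]] <- cf$indim
        cache$act[[l]] <- x
      }
    } else if (spec$kind == "pool") {
      if (keep) cache$indim[[l]] <- dim(x)
      x <- avgpool2_forward(x)
    } else if (spec$kind == "gap") {
      if (keep) cache$indim[[l]] <- dim(x)
      x <- gap_forward(x)
    } else if (spec$kind == "flatten") {
      if (keep) cache$indim[[l]] <- dim(x)
      x <- flatten_forward(x)
    } else if (spec$kind == "linear") {
      if (!is.matrix(x)) x <- flatten_forward(x)
      if (keep) cache$xin[[l]] <- x
      x <- wl$W %*% x
      if (l < L) {
        x <- relu(x)
        if (keep) cache$act[[l]] <- x
      }
    }
    if (l %in% record_layers) records[[as.character(l)]] <- x
  }
  list(logits = x, records = records, cache = cache)
}

ann_backward <- function(config, weights, fwd, dlogits, input_grad = FALSE,
                         act_grad_layer = NULL) {
  cache <- fwd$cache
  if (is.null(cache)) stopf("forward pass was not run with keep = TRUE")
  L <- length(config$layers)
  grads <- lapply(weights, function(wl) {
    if (!is.null(wl$W)) list(W = matrix(0, nrow(wl$W), ncol(wl$W))) else list()
  })
  dx <- dlogits
  act_grad <- NULL
  for (l in seq(L, 1L)) {
    spec <- config$layers[[l]]
    wl <- weights[[l]]
    if (spec$kind == "linear") {
      if (l < L) dx <- dx * (cache$act[[l]] > 0)
      grads[[l]]$W <- grads[[l]]$W + dx %*% t(cache$xin[[l]])
      dx <- crossprod(wl$W, dx)
    } else if (spec$kind == "gap") {
      dx <- gap_backward(dx, cache$indim[[l]])
    } else if (spec$kind == "flatten") {
      dx <- array(dx, cache$indim[[l]])
    } else if (spec$kind == "pool") {
      indim <- cache$indim[[l]]
      dout <- array(dx, c(indim[1], indim[2] / 2, indim[3] / 2, indim[4]))
      dx <- avgpool2_backward(dout, indim)
    } else if (spec$kind == "conv") {
      dx <- array(dx, dim(cache$act[[l]]))
      if (!is.null(act_grad_layer) && act_grad_layer == l) act_grad <- dx
      dx <- dx * (cache$act[[l]] > 0)
      cb <- conv2d_backward(dx, wl$W, cache$P[[l]], cache$indim[[l]],
                            spec$kernel, spec$kernel)
      grads[[l]]$W <- grads[[l]]$W + cb$dW
      dx <- cb$dx
    }
  }
  list(grads = grads, input_grad = if (input_grad) dx else NULL,
       act_grad = act_grad)
}
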