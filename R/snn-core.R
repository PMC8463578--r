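# Discrete-time leaky integrate-and-fire network simulator.
#
# The membrane update is the soft-reset LIF recurrence
#   u_t = lambda * u_{t-1} + drive_t - theta * o_{t-1}
#   o_t = 1  if u_t > theta, else 0
# i.e. the potential is integrated first, the spike is decided from the
# freshly updated potential, and the reset (subtracting theta) is applied in
# the following update via the previous-step spike flag. The output layer is a
# pure accumulator (lambda = 1, infinite threshold): its final potentials are
# the logits summed over all time-steps.

#' LIF neuron parameters
#'
#' @param leak Leak factor \eqn{\lambda \in [0, 1]} applied to the membrane
#'   potential at every step.
#' @param threshold Firing threshold \eqn{\theta > 0}. `Inf` marks a
#'   non-firing accumulator (used for the output layer).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(leak, threshold) {
  if (!is.numeric(leak) || length(leak) != 1L || is.na(leak) ||
      leak < 0 || leak > 1) {
    stopf("leak must be a single value in [0, 1]")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0) {
    stopf("threshold must be a single positive value (Inf allowed)")
  }
  structure(list(leak = leak, threshold = threshold), class = "neuron_params")
}

#' One LIF membrane update
#'
#' Applies the soft-reset leaky integrate-and-fire recurrence to a whole layer
#' at once. The reset term uses the *previous* step's spikes, so a neuron's
#' potential is never reduced at the same step in which it fires.
#'
#' @param state List with elements `potential` and `last_spike`, same shape.
#' @param weighted_input Per-neuron drive (weighted presynaptic input), same
#'   shape as the state.
#' @param params A [neuron_params()] object.
#' @return List with the updated `state` and the emitted binary `spikes`.
#' @examples
#' st <- list(potential = 0, last_spike = 0)
#' p <- neuron_params(1, 1)
#' r <- lif_update(st, 0.6, p)           # u = 0.6, no spike
#' r <- lif_update(r$state, 0.6, p)      # u = 1.2, spike
#' r <- lif_update(r$state, 0.6, p)      # u = 1.2 + 0.6 - 1 = 0.8
#' @export
lif_update <- function(state, weighted_input, params) {
  if (!inherits(params, "neuron_params")) params <- do.call(neuron_params, params)
  if (length(state$potential) != length(weighted_input) ||
      length(state$potential) != length(state$last_spike)) {
    stopf("state and weighted_input shapes do not match")
  }
  assert_finite(weighted_input, "weighted_input")
  u <- params$leak * state$potential + weighted_input
  if (is.finite(params$threshold)) {
    u <- u - params$threshold * state$last_spike
  }
  spikes <- (u > params$threshold) * 1
  list(state = list(potential = u, last_spike = spikes), spikes = spikes)
}

#' Batch normalization through time (BNTT)
#'
#' Normalizes a per-channel drive with statistics and a learnable scale that
#' are separate for every time-step; there is no additive shift term. In
#' `train` mode the mini-batch statistics for step `t` are used (and returned
#' so running statistics can be updated); in `eval` mode the stored running
#' statistics are used, making the operation a deterministic per-(channel, t)
#' affine map.
#'
#' @param preactivation Array `(C, H, W, B)` or matrix `C x B` of weighted
#'   presynaptic input.
#' @param params List with `gamma`, `running_mean`, `running_var` (each a
#'   `C x T` matrix) and `eps`.
#' @param t Time-step index in `1..T`.
#' @param mode `"train"` or `"eval"`.
#' @return List with `out` (normalized drive), and in train mode
#'   `batch_mean`, `batch_var` and a backward `cache`.
#' @export
bntt_normalize <- function(preactivation, params, t, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (t < 1L || t > ncol(params$gamma)) stopf("time-step %d out of range", t)
  d <- dim(preactivation)
  cdim <- if (is.null(d)) length(preactivation) else d[1]
  xm <- matrix(preactivation, nrow = cdim)
  if (mode == "train") {
    if (ncol(xm) < 2L) stopf("train mode needs at least 2 values per channel")
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc * xc)  # population variance over batch x space
  } else {
    mu <- params$running_mean[, t]
    va <- params$running_var[, t]
    xc <- xm - mu
  }
  invs <- 1 / sqrt(va + params$eps)
  xhat <- xc * invs
  out <- params$gamma[, t] * xhat
  if (!is.null(d)) dim(out) <- d
  res <- list(out = out)
  if (mode == "train") {
    res$batch_mean <- mu
    res$batch_var <- va
    res$cache <- list(xhat = xhat, invs = invs, dims = d)
  }
  res
}

bntt_backward <- function(dout, params, t, cache) {
  d <- cache$dims
  dm <- matrix(dout, nrow = nrow(params$gamma))
  dgamma_t <- rowSums(dm * cache$xhat)
  dxhat <- dm * params$gamma[, t]
  m <- ncol(dm)
  dx <- (cache$invs / m) *
    (m * dxhat - cache$xhat * rowSums(dxhat * cache$xhat) - rowSums(dxhat))
  if (!is.null(d)) dim(dx) <- d
  list(dx = dx, dgamma_t = dgamma_t)
}

# Eval-mode BNTT backward: affine, gradient is gamma / sqrt(var + eps).
bntt_backward_eval <- function(dout, params, t) {
  scale <- params$gamma[, t] / sqrt(params$running_var[, t] + params$eps)
  d <- dim(dout)
  dm <- matrix(dout, nrow = nrow(params$gamma)) * scale
  if (!is.null(d)) dim(dm) <- d
  dm
}

# --- network configuration --------------------------------------------------

#' Layer specification helpers
#'
#' Build the layer list for [network_config()]. Convolutions use stride 1 and
#' zero "same" padding; pooling is 2x2 average pooling applied to spikes (the
#' fractional output feeds the next layer's drive); `gap_layer()` is global
#' average pooling over space. The final layer must be a `linear_layer` with
#' an accumulator parameterization (`leak = 1`, `threshold = Inf`).
#'
#' @param out_channels,out_features Output width of the layer.
#' @param kernel Odd convolution kernel size.
#' @param params A [neuron_params()] object for the layer's LIF neurons.
#' @param bntt Whether to normalize the drive with BNTT before the LIF update.
#' @name layer_spec
NULL

#' @rdname layer_spec
#' @export
conv_layer <- function(out_channels, kernel = 3L,
                       params = neuron_params(0.99, 1), bntt = TRUE) {
  if (kernel %% 2L != 1L) stopf("kernel size must be odd")
  list(kind = "conv", out_channels = as.integer(out_channels),
       kernel = as.integer(kernel), params = params, bntt = isTRUE(bntt))
}

#' @rdname layer_spec
#' @export
pool_layer <- function() list(kind = "pool")

#' @rdname layer_spec
#' @export
gap_layer <- function() list(kind = "gap")

#' @rdname layer_spec
#' @export
flatten_layer <- function() list(kind = "flatten")

#' @rdname layer_spec
#' @export
linear_layer <- function(out_features, params = neuron_params(1, Inf)) {
  list(kind = "linear", out_features = as.integer(out_features),
       params = params)
}

#' Network configuration
#'
#' @param layers List of layer specs built with the [layer_spec] helpers.
#' @param timesteps Total number of simulation steps `T >= 1`.
#' @param num_classes Number of output classes `C >= 2`.
#' @param input_shape Integer vector `(channels, rows, cols)` of the input.
#' @return An object of class `network_config`.
#' @export
network_config <- function(layers, timesteps, num_classes, input_shape) {
  timesteps <- as.integer(timesteps)
  num_classes <- as.integer(num_classes)
  if (timesteps < 1L) stopf("timesteps must be >= 1")
  if (num_classes < 2L) stopf("num_classes must be >= 2")
  if (length(input_shape) != 3L) stopf("input_shape must be (channels, rows, cols)")
  last <- layers[[length(layers)]]
  if (last$kind != "linear" || is.finite(last$params$threshold) ||
      last$params$leak != 1) {
    stopf("final layer must be a linear accumulator (leak 1, infinite threshold)")
  }
  if (last$out_features != num_classes) {
    stopf("final layer width must equal num_classes")
  }
  structure(list(layers = layers, timesteps = timesteps,
                 num_classes = num_classes,
                 input_shape = as.integer(input_shape)),
            class = "network_config")
}

#' Default desk-scale architecture
#'
#' Three BNTT convolution layers (8/16/16 channels) with 2x2 average pooling
#' after the first two, global average pooling, and a linear accumulator
#' classifier. This preserves the shallow/mid/deep layer structure of larger
#' VGG-style networks at a size trainable on one CPU.
#'
#' @param in_channels,image_size Input geometry.
#' @param num_classes Number of classes.
#' @param timesteps Simulation length `T`.
#' @param leak Hidden-layer leak factor (1 for converted networks).
#' @param threshold Hidden-layer firing threshold.
#' @param bntt Whether hidden conv layers carry BNTT (off for conversion).
#' @return A [network_config()].
#' @export
default_network_config <- function(in_channels = 1L, image_size = 16L,
                                   num_classes = 4L, timesteps = 20L,
                                   leak = 0.99, threshold = 1, bntt = TRUE) {
  p <- function() neuron_params(leak, threshold)
  network_config(
    layers = list(
      conv_layer(8L, 3L, p(), bntt = bntt),
      pool_layer(),
      conv_layer(16L, 3L, p(), bntt = bntt),
      pool_layer(),
      conv_layer(16L, 3L, p(), bntt = bntt),
      gap_layer(),
      linear_layer(num_classes)
    ),
    timesteps = timesteps, num_classes = num_classes,
    input_shape = c(in_channels, image_size, image_size)
  )
}

# Track (channels, rows, cols) / feature-count through the layer stack.
# Returns a list with, per layer, $in_shape and $out_shape (either a length-3
# spatial shape or a single feature count).
layer_shapes <- function(config, input_shape = config$input_shape) {
  shp <- as.numeric(input_shape)
  out <- vector("list", length(config$layers))
  for (l in seq_along(config$layers)) {
    spec <- config$layers[[l]]
    inshape <- shp
    shp <- switch(spec$kind,
      conv = c(spec$out_channels, shp[2], shp[3]),
      pool = c(shp[1], shp[2] / 2, shp[3] / 2),
      gap = shp[1],
      flatten = prod(shp),
      linear = spec$out_features,
      stopf("unknown layer kind '%s'", spec$kind)
    )
    out[[l]] <- list(in_shape = inshape, out_shape = shp)
  }
  out
}

#' Initialize network weights
#'
#' He-style Gaussian initialization for convolution and linear weights; BNTT
#' scale initialized to 1 with zero running mean and unit running variance.
#'
#' @param config A [network_config()].
#' @param seed Integer RNG seed.
#' @return A list of per-layer weight entries aligned with `config$layers`.
#' @export
init_network <- function(config, seed = 1L) {
  shapes <- layer_shapes(config)
  with_seed(seed, {
    lapply(seq_along(config$layers), function(l) {
      spec <- config$layers[[l]]
      if (spec$kind == "conv") {
        cin <- shapes[[l]]$in_shape[1]
        fan <- cin * spec$kernel^2
        w <- list(W = matrix(stats::rnorm(spec$out_channels * fan,
                                          sd = sqrt(2 / fan)),
                             spec$out_channels, fan))
        if (spec$bntt) {
          ch <- spec$out_channels
          w$bntt <- list(gamma = matrix(1, ch, config$timesteps),
                         running_mean = matrix(0, ch, config$timesteps),
                         running_var = matrix(1, ch, config$timesteps),
                         eps = 1e-5)
        }
        w
      } else if (spec$kind == "linear") {
        fan <- shapes[[l]]$in_shape[1]
        if (length(shapes[[l]]$in_shape) > 1L) fan <- prod(shapes[[l]]$in_shape)
        list(W = matrix(stats::rnorm(spec$out_features * fan,
                                     sd = sqrt(1 / fan)),
                        spec$out_features, fan))
      } else {
        list()
      }
    })
  })
}

# Indices of layers that carry LIF state (conv and linear layers).
lif_layer_indices <- function(config) {
  which(vapply(config$layers, function(s) s$kind %in% c("conv", "linear"),
               logical(1)))
}

# --- forward engine ---------------------------------------------------------

# Internal batched forward pass. raster: (T, C, H, W, B). Options:
#   record_layers: spike rasters (T, C, H, W, B) kept for these layer indices
#   keep: cache everything needed for BPTT
#   bntt_mode: "eval" uses running stats; "train" uses batch stats and
#              returns momentum-updated running stats in $weights
#   drive_max_layer: track the max pre-activation (pre-BNTT drive) at a layer
snn_forward <- function(config, weights, raster, record_layers = integer(),
                        keep = FALSE, bntt_mode = "eval",
                        drive_max_layer = NULL, bntt_momentum = 0.1) {
  dr <- dim(raster)
  if (length(dr) != 5L) stopf("internal forward expects (T,C,H,W,B)")
  T <- dr[1]
  if (T != config$timesteps) stopf("raster T (%d) != config timesteps (%d)", T, config$timesteps)
  B <- dr[5]
  L <- length(config$layers)
  lif_idx <- lif_layer_indices(config)

  u_state <- vector("list", L)
  o_state <- vector("list", L)
  records <- list()
  cache <- if (keep) list(u = vector("list", L), o = vector("list", L),
                          P = vector("list", L), xin = vector("list", L),
                          bn = vector("list", L), indim = vector("list", L),
                          input_dim = dr) else NULL
  if (keep) {
    for (l in lif_idx) {
      cache$u[[l]] <- vector("list", T)
      cache$o[[l]] <- vector("list", T)
      cache$P[[l]] <- vector("list", T)
      cache$xin[[l]] <- vector("list", T)
      cache$bn[[l]] <- vector("list", T)
    }
  }
  drive_max <- -Inf
  out_potential <- NULL

  for (t in seq_len(T)) {
    x <- raster[t, , , , , drop = FALSE]
    dim(x) <- dr[-1]
    for (l in seq_len(L)) {
      spec <- config$layers[[l]]
      wl <- weights[[l]]
      if (spec$kind == "conv") {
        cf <- conv2d_forward(x, wl$W, spec$kernel, spec$kernel)
        drive <- cf$out
        if (!is.null(drive_max_layer) && drive_max_layer == l) {
          drive_max <- max(drive_max, max(drive))
        }
        if (keep) {
          cache$P[[l]][[t]] <- cf$P
          cache$indim[[l]] <- cf$indim
        }
        if (spec$bntt) {
          bn <- bntt_normalize(drive, wl$bntt, t, mode = bntt_mode)
          drive <- bn$out
          if (bntt_mode == "train") {
            rm_ <- wl$bntt$running_mean[, t]
            rv_ <- wl$bntt$running_var[, t]
            weights[[l]]$bntt$running_mean[, t] <-
              (1 - bntt_momentum) * rm_ + bntt_momentum * bn$batch_mean
            weights[[l]]$bntt$running_var[, t] <-
              (1 - bntt_momentum) * rv_ + bntt_momentum * bn$batch_var
            if (keep) cache$bn[[l]][[t]] <- bn$cache
          }
        }
        if (is.null(u_state[[l]])) {
          u_state[[l]] <- array(0, dim(drive))
          o_state[[l]] <- array(0, dim(drive))
        }
        st <- lif_update(list(potential = u_state[[l]], last_spike = o_state[[l]]),
                         drive, spec$params)
        u_state[[l]] <- st$state$potential
        o_state[[l]] <- st$state$last_spike
        if (keep) {
          cache$u[[l]][[t]] <- u_state[[l]]
          cache$o[[l]][[t]] <- o_state[[l]]
        }
        x <- st$spikes
        dim(x) <- dim(drive)
      } else if (spec$kind == "pool") {
        x <- avgpool2_forward(x)
      } else if (spec$kind == "gap") {
        x <- gap_forward(x)
      } else if (spec$kind == "flatten") {
        x <- flatten_forward(x)
      } else if (spec$kind == "linear") {
        if (!is.matrix(x)) x <- flatten_forward(x)
        if (keep) cache$xin[[l]][[t]] <- x
        drive <- wl$W %*% x
        if (!is.null(drive_max_layer) && drive_max_layer == l) {
          drive_max <- max(drive_max, max(drive))
        }
        if (is.null(u_state[[l]])) {
          u_state[[l]] <- matrix(0, nrow(drive), ncol(drive))
          o_state[[l]] <- matrix(0, nrow(drive), ncol(drive))
        }
        st <- lif_update(list(potential = u_state[[l]], last_spike = o_state[[l]]),
                         drive, spec$params)
        u_state[[l]] <- st$state$potential
        o_state[[l]] <- st$state$last_spike
        if (keep) {
          cache$u[[l]][[t]] <- u_state[[l]]
          cache$o[[l]][[t]] <- o_state[[l]]
        }
        x <- st$spikes
      }
      if (l %in% record_layers) {
        key <- as.character(l)
        if (is.null(records[[key]])) {
          records[[key]] <- array(0, c(T, dim(x)))
        }
        rec <- records[[key]]
        slice <- array(x, c(1L, dim(x)))
        if (length(dim(x)) == 4L) rec[t, , , , ] <- slice else rec[t, , ] <- slice
        records[[key]] <- rec
      }
    }
    out_potential <- u_state[[L]]
  }
  list(potentials = out_potential, records = records, cache = cache,
       weights = weights, drive_max = drive_max)
}

# Internal BPTT backward pass through a cached forward run.
# dlogits: C x B gradient w.r.t. the accumulated output potentials.
# Returns gradients mirroring the weight structure, and optionally the
# gradient w.r.t. the input raster summed over time (for FGSM) and the
# per-time-step gradient w.r.t. a layer's output spikes (for Grad-CAM alpha).
snn_backward <- function(config, weights, fwd, dlogits,
                         input_grad = FALSE, spike_grad_layer = NULL,
                         bntt_mode = "eval") {
  cache <- fwd$cache
  if (is.null(cache)) stopf("forward pass was not run with keep = TRUE")
  T <- config$timesteps
  L <- length(config$layers)
  B <- cache$input_dim[5]
  shapes <- layer_shapes(config, cache$input_dim[2:4])
  in_dim <- function(l) c(shapes[[l]]$in_shape, B)
  grads <- lapply(weights, function(wl) {
    g <- list()
    if (!is.null(wl$W)) g$W <- matrix(0, nrow(wl$W), ncol(wl$W))
    if (!is.null(wl$bntt)) g$dgamma <- matrix(0, nrow(wl$bntt$gamma), T)
    g
  })
  du_next <- vector("list", L)
  x_grad <- NULL
  spike_grads <- NULL

  for (t in seq(T, 1L)) {
    dx <- NULL  # gradient flowing down; NULL until set by the output layer
    for (l in seq(L, 1L)) {
      spec <- config$layers[[l]]
      wl <- weights[[l]]
      if (spec$kind == "linear") {
        if (l == L) {
          ddrive <- dlogits  # accumulator with leak 1: dL/d drive_t = dL/d u_T
        } else {
          do_t <- dx
          if (is.finite(spec$params$threshold) && !is.null(du_next[[l]])) {
            do_t <- do_t - spec$params$threshold * du_next[[l]]
          }
          sg <- surrogate_grad(cache$u[[l]][[t]], spec$params$threshold)
          du <- do_t * sg
          if (!is.null(du_next[[l]])) du <- du + spec$params$leak * du_next[[l]]
          du_next[[l]] <- du
          ddrive <- du
        }
        grads[[l]]$W <- grads[[l]]$W + ddrive %*% t(cache$xin[[l]][[t]])
        dx <- crossprod(wl$W, ddrive)
      } else if (spec$kind == "gap") {
        dx <- gap_backward(dx, in_dim(l))
      } else if (spec$kind == "flatten") {
        dx <- array(dx, in_dim(l))
      } else if (spec$kind == "pool") {
        indim <- in_dim(l)
        dout <- array(dx, c(indim[1], indim[2] / 2, indim[3] / 2, indim[4]))
        dx <- avgpool2_backward(dout, indim)
      } else if (spec$kind == "conv") {
        do_t <- dx
        if (is.finite(spec$params$threshold) && !is.null(du_next[[l]])) {
          do_t <- do_t - spec$params$threshold * du_next[[l]]
        }
        if (!is.null(spike_grad_layer) && spike_grad_layer == l) {
          if (is.null(spike_grads)) {
            spike_grads <- array(0, c(T, dim(do_t)))
          }
          spike_grads[t, , , , ] <- array(do_t, c(1L, dim(do_t)))
        }
        sg <- surrogate_grad(cache$u[[l]][[t]], spec$params$threshold)
        du <- do_t * sg
        if (!is.null(du_next[[l]])) du <- du + spec$params$leak * du_next[[l]]
        du_next[[l]] <- du
        ddrive <- du
        if (spec$bntt) {
          if (bntt_mode == "train") {
            bb <- bntt_backward(ddrive, wl$bntt, t, cache$bn[[l]][[t]])
            grads[[l]]$dgamma[, t] <- grads[[l]]$dgamma[, t] + bb$dgamma_t
            ddrive <- bb$dx
          } else {
            ddrive <- bntt_backward_eval(ddrive, wl$bntt, t)
          }
        }
        cb <- conv2d_backward(ddrive, wl$W, cache$P[[l]][[t]],
                              cache$indim[[l]], spec$kernel, spec$kernel)
        grads[[l]]$W <- grads[[l]]$W + cb$dW
        dx <- cb$dx
      }
    }
    if (input_grad) {
      x_grad <- if (is.null(x_grad)) dx else x_grad + dx
    }
  }
  list(grads = grads, input_grad = x_grad, spike_grads = spike_grads)
}

#' Simulate a spiking network on an input spike raster
#'
#' Runs the full discrete-time LIF simulation for `T` steps, optionally
#' recording full spike rasters at selected layers, and accumulates the output
#' layer's potentials (its leak is 1 and its threshold infinite, so the final
#' potentials are the summed logits). The run is deterministic given the
#' weights and the input raster.
#'
#' @param config A [network_config()].
#' @param weights Weights from [init_network()], [train_snn()] or
#'   [convert_ann_to_snn()].
#' @param input_raster Binary array `(T, C, H, W)` for a single sample, or
#'   `(T, C, H, W, B)` for a batch.
#' @param record_layers Integer indices (into `config$layers`) of LIF layers
#'   whose spike rasters should be recorded.
#' @return List with `potentials` (length-`C` vector, or `C x B` matrix for a
#'   batch) and `records`, a named list of spike rasters shaped like the
#'   input convention (`(T, K, H, W)` per sample).
#' @export
forward_network <- function(config, weights, input_raster,
                            record_layers = integer()) {
  d <- dim(input_raster)
  single <- length(d) == 4L
  if (single) {
    dim(input_raster) <- c(d, 1L)
    d <- dim(input_raster)
  }
  if (length(d) != 5L) stopf("input raster must be (T,C,H,W) or (T,C,H,W,B)")
  assert_binary(input_raster, "input raster")
  lif_idx <- lif_layer_indices(config)
  if (length(record_layers) && !all(record_layers %in% lif_idx)) {
    stopf("record_layers must index conv/linear (LIF) layers")
  }
  fwd <- snn_forward(config, weights, input_raster,
                     record_layers = record_layers)
  records <- fwd$records
  potentials <- fwd$potentials
  if (single) {
    potentials <- drop(potentials)
    records <- lapply(records, function(r) {
      dd <- dim(r)
      array(r, dd[-length(dd)])
    })
  }
  list(potentials = potentials, records = records)
}

# --- serialization ----------------------------------------------------------

# Flatten a weights list into uniquely named arrays (one per parameter
# tensor) for the array-container bundle.
weights_to_arrays <- function(weights) {
  out <- list()
  for (l in seq_along(weights)) {
    wl <- weights[[l]]
    if (!is.null(wl$W)) out[[sprintf("layer%02d.W", l)]] <- wl$W
    if (!is.null(wl$bntt)) {
      out[[sprintf("layer%02d.bntt.gamma", l)]] <- wl$bntt$gamma
      out[[sprintf("layer%02d.bntt.running_mean", l)]] <- wl$bntt$running_mean
      out[[sprintf("layer%02d.bntt.running_var", l)]] <- wl$bntt$running_var
    }
  }
  out
}

arrays_to_weights <- function(arrays, config) {
  lapply(seq_along(config$layers), function(l) {
    wl <- list()
    key <- sprintf("layer%02d.W", l)
    if (!is.null(arrays[[key]])) wl$W <- arrays[[key]]
    gkey <- sprintf("layer%02d.bntt.gamma", l)
    if (!is.null(arrays[[gkey]])) {
      wl$bntt <- list(gamma = arrays[[gkey]],
                      running_mean = arrays[[sprintf("layer%02d.bntt.running_mean", l)]],
                      running_var = arrays[[sprintf("layer%02d.bntt.running_var", l)]],
                      eps = 1e-5)
    }
    wl
  })
}

config_to_manifest <- function(config) {
  list(timesteps = config$timesteps, num_classes = config$num_classes,
       input_shape = config$input_shape,
       layers = lapply(config$layers, function(s) {
         m <- list(kind = s$kind)
         if (s$kind == "conv") {
           m$out_channels <- s$out_channels
           m$kernel <- s$kernel
           m$bntt <- s$bntt
         }
         if (s$kind == "linear") m$out_features <- s$out_features
         if (!is.null(s$params)) {
           m$leak <- s$params$leak
           m$threshold <- if (is.finite(s$params$threshold)) s$params$threshold else "Inf"
         }
         m
       }))
}

manifest_to_config <- function(m) {
  layers <- lapply(m$layers, function(s) {
    th <- if (identical(s$threshold, "Inf")) Inf else as.numeric(s$threshold)
    switch(s$kind,
      conv = conv_layer(s$out_channels, s$kernel,
                        neuron_params(s$leak, th), bntt = isTRUE(s$bntt)),
      pool = pool_layer(),
      gap = gap_layer(),
      flatten = flatten_layer(),
      linear = linear_layer(s$out_features, neuron_params(s$leak, th)))
  })
  network_config(layers, m$timesteps, m$num_classes, unlist(m$input_shape))
}

#' Save / load a network checkpoint
#'
#' Stores one named array per parameter tensor plus a structured manifest of
#' the network configuration in a single portable bundle file.
#'
#' @param path Bundle file path.
#' @param config A [network_config()].
#' @param weights The network weights.
#' @return `load_network()` returns `list(config, weights)`.
#' @export
save_network <- function(path, config, weights) {
  save_bundle(path, weights_to_arrays(weights),
              manifest = list(network = config_to_manifest(config)))
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  b <- load_bundle(path)
  config <- manifest_to_config(b$manifest$network)
  list(config = config, weights = arrays_to_weights(b$arrays, config))
}
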