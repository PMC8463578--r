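# Obtaining desk-scale explainable networks: surrogate-gradient training with
# BNTT from scratch, training of the reference ReLU ANN, and ANN-to-SNN
# conversion by layerwise threshold normalization.

#' Training configuration
#'
#' Defaults mirror common SNN practice at desk scale: SGD with momentum 0.9
#' and weight decay 5e-4, step learning-rate decay by 10x at 50/70/90% of the
#' epoch budget, leak 0.99 for surrogate training. The seed fixes all
#' stochasticity (initialization, Poisson coding, shuffling).
#'
#' @param epochs,batch_size,lr,momentum,weight_decay SGD hyperparameters.
#' @param lr_decay_at Fractions of the epoch budget at which the learning
#'   rate is divided by 10.
#' @param timesteps Simulation length `T` used during training.
#' @param leak Hidden-layer leak factor.
#' @param seed Integer RNG seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 12L, batch_size = 32L, lr = 0.1,
                         momentum = 0.9, weight_decay = 5e-4,
                         lr_decay_at = c(0.5, 0.7, 0.9),
                         timesteps = 20L, leak = 0.99, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              lr = lr, momentum = momentum, weight_decay = weight_decay,
              lr_decay_at = lr_decay_at, timesteps = as.integer(timesteps),
              leak = leak, seed = as.integer(seed))
  if (any(unlist(cfg[c("epochs", "batch_size", "lr")]) < 0)) {
    stopf("training hyperparameters must be non-negative")
  }
  structure(cfg, class = "train_config")
}

#' Cross-entropy loss on accumulated output potentials
#'
#' Softmax over the output layer's potentials accumulated across all `T`
#' steps, then the negative log-likelihood of the true class.
#'
#' @param output_potentials Length-`C` vector of accumulated potentials.
#' @param label True class index (1-based).
#' @param num_classes Class count `C >= 2`.
#' @return Scalar loss.
#' @export
snn_loss <- function(output_potentials, label, num_classes = length(output_potentials)) {
  if (num_classes < 2L) stopf("need at least 2 classes")
  if (label < 1L || label > num_classes) stopf("label out of range")
  assert_finite(output_potentials, "output potentials")
  z <- output_potentials - max(output_potentials)
  log(sum(exp(z))) - z[label]
}

# Batch loss + gradient: potentials C x B, labels length B.
ce_loss_grad <- function(potentials, labels) {
  p <- softmax_cols(potentials)
  B <- ncol(potentials)
  idx <- cbind(labels, seq_len(B))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / B,
       pred = apply(potentials, 2, which.max))
}

sgd_init <- function(weights) {
  lapply(weights, function(wl) {
    v <- list()
    if (!is.null(wl$W)) v$W <- wl$W * 0
    if (!is.null(wl$bntt)) v$gamma <- wl$bntt$gamma * 0
    v
  })
}

sgd_update <- function(weights, grads, vel, lr, momentum, weight_decay) {
  for (l in seq_along(weights)) {
    if (!is.null(weights[[l]]$W)) {
      g <- grads[[l]]$W + weight_decay * weights[[l]]$W
      vel[[l]]$W <- momentum * vel[[l]]$W + g
      weights[[l]]$W <- weights[[l]]$W - lr * vel[[l]]$W
    }
    if (!is.null(weights[[l]]$bntt) && !is.null(grads[[l]]$dgamma)) {
      g <- grads[[l]]$dgamma + weight_decay * weights[[l]]$bntt$gamma
      vel[[l]]$gamma <- momentum * vel[[l]]$gamma + g
      weights[[l]]$bntt$gamma <- weights[[l]]$bntt$gamma - lr * vel[[l]]$gamma
    }
  }
  list(weights = weights, vel = vel)
}

epoch_lr <- function(cfg, epoch) {
  drops <- sum(epoch > ceiling(cfg$lr_decay_at * cfg$epochs))
  cfg$lr / 10^drops
}

dataset_images_array <- function(dataset, idx) {
  d <- dim(dataset$images)
  array(dataset$images[, , , idx, drop = FALSE], c(d[1:3], length(idx)))
}

#' Train a spiking network with surrogate gradients and BNTT
#'
#' SGD with momentum and weight decay on the cross-entropy loss over
#' accumulated output potentials; gradients flow back through all `T` steps
#' via the triangular surrogate derivative; BNTT layers use mini-batch
#' statistics per time-step during training. Fully deterministic given the
#' seed. Training aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param dataset A [make_shape_dataset()] (its `train` split is used).
#' @param config A [network_config()]; defaults to the desk-scale
#'   architecture sized to the dataset.
#' @param cfg A [train_config()].
#' @return List with trained `weights`, per-epoch `history`
#'   (epoch/loss/accuracy), and the `config` used.
#' @export
train_snn <- function(dataset, config = NULL, cfg = train_config()) {
  if (is.null(config)) {
    config <- default_network_config(
      in_channels = dim(dataset$images)[1],
      image_size = dim(dataset$images)[2],
      num_classes = dataset$n_classes,
      timesteps = cfg$timesteps, leak = cfg$leak)
  }
  idx_train <- which(dataset$split == "train")
  labels <- dataset$labels[idx_train]
  history <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  with_seed(cfg$seed, {
    weights <- init_network(config, seed = NULL)
    vel <- sgd_init(weights)
    for (epoch in seq_len(cfg$epochs)) {
      lr <- epoch_lr(cfg, epoch)
      perm <- sample(length(idx_train))
      tot_loss <- 0
      tot_correct <- 0L
      nb <- 0L
      for (start in seq(1, length(perm), by = cfg$batch_size)) {
        bidx <- perm[start:min(start + cfg$batch_size - 1, length(perm))]
        if (length(bidx) < 2L) next  # BNTT needs batch statistics
        imgs <- dataset_images_array(dataset, idx_train[bidx])
        raster <- poisson_encode_batch(imgs, config$timesteps)
        fwd <- snn_forward(config, weights, raster, keep = TRUE,
                           bntt_mode = "train")
        weights <- fwd$weights  # running statistics updated
        lg <- ce_loss_grad(fwd$potentials, labels[bidx])
        if (!is.finite(lg$loss)) {
          stopf("training diverged at epoch %d (non-finite loss)", epoch)
        }
        bwd <- snn_backward(config, weights, fwd, lg$dlogits,
                            bntt_mode = "train")
        upd <- sgd_update(weights, bwd$grads, vel, lr, cfg$momentum,
                          cfg$weight_decay)
        weights <- upd$weights
        vel <- upd$vel
        tot_loss <- tot_loss + lg$loss
        tot_correct <- tot_correct + sum(lg$pred == labels[bidx])
        nb <- nb + 1L
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = if (nb) tot_loss / nb else NA_real_,
        accuracy = tot_correct / length(idx_train)))
    }
    list(weights = weights, history = history, config = config, cfg = cfg)
  })
}

#' Train the reference ReLU ANN
#'
#' Same topology, optimizer and determinism contract as [train_snn()], but on
#' analog inputs (`pixels / 255`) with ReLU activations and no temporal
#' dimension. Used as the Grad-CAM reference and as the conversion source.
#'
#' @inheritParams train_snn
#' @return List with trained `weights`, `history`, and `config`.
#' @export
train_ann <- function(dataset, config = NULL, cfg = train_config()) {
  if (is.null(config)) {
    config <- default_network_config(
      in_channels = dim(dataset$images)[1],
      image_size = dim(dataset$images)[2],
      num_classes = dataset$n_classes,
      timesteps = cfg$timesteps, bntt = FALSE)
  }
  idx_train <- which(dataset$split == "train")
  labels <- dataset$labels[idx_train]
  history <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  with_seed(cfg$seed, {
    weights <- init_network(config, seed = NULL)
    vel <- sgd_init(weights)
    for (epoch in seq_len(cfg$epochs)) {
      lr <- epoch_lr(cfg, epoch)
      perm <- sample(length(idx_train))
      tot_loss <- 0
      tot_correct <- 0L
      nb <- 0L
      for (start in seq(1, length(perm), by = cfg$batch_size)) {
        bidx <- perm[start:min(start + cfg$batch_size - 1, length(perm))]
        x <- dataset_images_array(dataset, idx_train[bidx]) / 255
        fwd <- ann_forward(config, weights, x, keep = TRUE)
        lg <- ce_loss_grad(fwd$logits, labels[bidx])
        if (!is.finite(lg$loss)) {
          stopf("training diverged at epoch %d (non-finite loss)", epoch)
        }
        bwd <- ann_backward(config, weights, fwd, lg$dlogits)
        upd <- sgd_update(weights, bwd$grads, vel, lr, cfg$momentum,
                          cfg$weight_decay)
        weights <- upd$weights
        vel <- upd$vel
        tot_loss <- tot_loss + lg$loss
        tot_correct <- tot_correct + sum(lg$pred == labels[bidx])
        nb <- nb + 1L
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = if (nb) tot_loss / nb else NA_real_,
        accuracy = tot_correct / length(idx_train)))
    }
    list(weights = weights, history = history, config = config, cfg = cfg)
  })
}

#' ANN predictions
#'
#' @param config,weights Trained ANN.
#' @param images Array `(C, H, W, B)` of pixel intensities in `[0, 255]`.
#' @return Integer vector of predicted class indices.
#' @export
ann_predict <- function(config, weights, images) {
  fwd <- ann_forward(config, weights, images / 255)
  apply(fwd$logits, 2, which.max)
}

#' Convert a trained ANN to a spiking network
#'
#' Copies the ANN weights unchanged and sets each LIF layer's firing
#' threshold, in order starting from the first layer, to the maximum
#' pre-activation observed while running Poisson-coded calibration inputs
#' through the partially converted network for `T` steps. The leak is fixed
#' to 1 and BNTT is off (spike inputs have zero-mean statistics that batch
#' normalization would distort).
#'
#' @param ann Result of [train_ann()] (list with `config` and `weights`).
#' @param calibration_images Array `(C, H, W, B)` of calibration inputs in
#'   `[0, 255]`.
#' @param timesteps Simulation length `T` of the converted network.
#' @param seed Seed for the Poisson coding of the calibration set.
#' @return List with `config`, `weights`, and a `report` data frame
#'   (layer, threshold, max activation) carrying the rate-vs-ReLU agreement
#'   correlation as attribute `"rate_relu_cor"`.
#' @export
convert_ann_to_snn <- function(ann, calibration_images, timesteps = 128L,
                               seed = 1L) {
  src <- ann$config
  layers <- lapply(src$layers, function(s) {
    if (s$kind == "conv") {
      conv_layer(s$out_channels, s$kernel, neuron_params(1, Inf), bntt = FALSE)
    } else if (s$kind == "linear") {
      s  # output accumulator kept as-is
    } else {
      s
    }
  })
  config <- network_config(layers, as.integer(timesteps), src$num_classes,
                           src$input_shape)
  weights <- lapply(ann$weights, function(wl) {
    if (!is.null(wl$W)) list(W = wl$W) else list()
  })
  raster <- with_seed(seed, poisson_encode_batch(calibration_images, timesteps))
  conv_idx <- which(vapply(config$layers, function(s) s$kind == "conv", logical(1)))
  report <- data.frame(layer = integer(), threshold = numeric(),
                       max_activation = numeric())
  for (l in conv_idx) {
    fwd <- snn_forward(config, weights, raster, drive_max_layer = l)
    if (!is.finite(fwd$drive_max) || fwd$drive_max <= 0) {
      stopf("layer %d never activates on the calibration set; cannot set a threshold", l)
    }
    config$layers[[l]]$params <- neuron_params(1, fwd$drive_max)
    report <- rbind(report, data.frame(layer = l, threshold = fwd$drive_max,
                                       max_activation = fwd$drive_max))
  }
  # rate-vs-ReLU agreement: firing rates at the last conv layer vs the ANN's
  # ReLU activations on the calibration inputs
  last_conv <- conv_idx[length(conv_idx)]
  fw <- snn_forward(config, weights, raster, record_layers = last_conv)
  rec <- fw$records[[as.character(last_conv)]]
  rates <- array(colMeans(matrix(rec, nrow = dim(rec)[1])), dim(rec)[-1])
  af <- ann_forward(ann$config, ann$weights, calibration_images / 255,
                    keep = TRUE, record_layers = last_conv)
  acts <- af$records[[as.character(last_conv)]]
  attr(report, "rate_relu_cor") <- stats::cor(as.numeric(rates), as.numeric(acts))
  list(config = config, weights = weights, report = report)
}

#' SNN predictions by Poisson-coded forward simulation
#'
#' @param config,weights Trained or converted SNN.
#' @param images Array `(C, H, W, B)` in `[0, 255]`.
#' @param seed Seed for the Poisson coding.
#' @param chunk Batch chunk size to bound memory at large `T`.
#' @return Integer vector of predicted class indices.
#' @export
snn_predict <- function(config, weights, images, seed = 1L, chunk = 64L) {
  d <- dim(images)
  with_seed(seed, {
    preds <- integer(d[4])
    for (start in seq(1, d[4], by = chunk)) {
      idx <- start:min(start + chunk - 1, d[4])
      raster <- poisson_encode_batch(
        array(images[, , , idx, drop = FALSE], c(d[1:3], length(idx))),
        config$timesteps)
      fwd <- snn_forward(config, weights, raster)
      preds[idx] <- apply(fwd$potentials, 2, which.max)
    }
    preds
  })
}
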