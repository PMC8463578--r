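# Shared trained fixtures for the acceptance tests. Built lazily on first use
# and cached for the whole run; everything is generated in code under fixed
# seeds (the stated desk-scale world: 4 glyph classes, 16x16 images,
# 300 train / 100 test images, noise level 0.3, 3-conv network,
# T = 20 surrogate / T = 128 converted).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fix_dataset <- function() {
  fixture("dataset", function() {
    make_shape_dataset(n_classes = 4L, image_size = 16L, n_per_class = 100L,
                       noise_level = 0.3, seed = 20210924L, train_frac = 0.75)
  })
}

fix_ann <- function() {
  fixture("ann", function() {
    train_ann(fix_dataset(), cfg = train_config(epochs = 60L, lr = 0.1, seed = 2L))
  })
}

fix_snn <- function() {
  fixture("snn", function() {
    train_snn(fix_dataset(),
              cfg = train_config(epochs = 30L, lr = 0.02, timesteps = 20L,
                                 leak = 0.99, seed = 2L))
  })
}

fix_converted <- function() {
  fixture("converted", function() {
    ds <- fix_dataset()
    idx <- which(ds$split == "train")[1:64]
    calib <- array(ds$images[, , , idx], c(dim(ds$images)[1:3], 64L))
    convert_ann_to_snn(fix_ann(), calib, timesteps = 128L, seed = 7L)
  })
}

fix_test_indices <- function() which(fix_dataset()$split == "test")

fix_image <- function(i) {
  ds <- fix_dataset()
  array(ds$images[, , , i], dim(ds$images)[1:3])
}

# Shared localization-error table for the gamma-sweep and layer-depth
# criteria: per test image, per network, per probed conv layer, per gamma.
fix_trend_errors <- function() {
  fixture("trend_errors", function() {
    ds <- fix_dataset()
    ann <- fix_ann()
    nets <- list(surrogate = fix_snn(), converted = fix_converted())
    idx <- fix_test_indices()[1:50]
    layers <- c(1L, 3L, 5L)
    gammas <- c(0, 0.2, 1.0)
    err <- array(NA_real_, c(length(idx), 2L, 3L, 3L),
                 dimnames = list(NULL, names(nets), paste0("layer", layers),
                                 paste0("gamma", gammas)))
    for (k in seq_along(idx)) {
      i <- idx[k]
      img <- fix_image(i)
      refs <- lapply(layers, function(l) {
        ann_gradcam(ann$config, ann$weights, img, ds$labels[i], l)
      })
      for (mi in seq_along(nets)) {
        net <- nets[[mi]]
        raster <- poisson_encode(img, net$config$timesteps, seed = 1000L + i)
        fw <- forward_network(net$config, net$weights, raster,
                              record_layers = layers)
        for (li in seq_along(layers)) {
          rec <- fw$records[[as.character(layers[li])]]
          for (gi in seq_along(gammas)) {
            sam <- normalize_heatmaps(compute_sam(rec, gammas[gi]))
            err[k, mi, li, gi] <- localization_error(sam, refs[[li]])$error
          }
        }
      }
    }
    err
  })
}
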