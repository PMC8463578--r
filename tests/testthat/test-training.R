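tiny_dataset <- function(seed = 3L) {
  make_shape_dataset(n_classes = 2L, image_size = 12L, n_per_class = 12L,
                     noise_level = 0.2, seed = seed, train_frac = 0.75)
}

tiny_net <- function(ds, timesteps = 6L, bntt = TRUE) {
  network_config(
    list(conv_layer(4L, 3L, neuron_params(0.99, 1), bntt = bntt),
         pool_layer(), gap_layer(), linear_layer(ds$n_classes)),
    timesteps = timesteps, num_classes = ds$n_classes,
    input_shape = c(1L, ds$image_size, ds$image_size))
}

test_that("snn_loss matches softmax cross-entropy closed forms", {
  expect_equal(snn_loss(rep(1.3, 4), 2), log(4))
  expect_equal(snn_loss(c(2, 0), 1), log(1 + exp(-2)))
  expect_lt(snn_loss(c(50, 0, 0), 1), 1e-12)
  expect_error(snn_loss(c(1, 2), 3), "label")
  expect_error(snn_loss(c(NaN, 1), 1), "non-finite")
})

test_that("training is deterministic and the loss decreases early", {
  ds <- tiny_dataset()
  net <- tiny_net(ds)
  cfg <- train_config(epochs = 3L, batch_size = 9L, lr = 0.02,
                      timesteps = 6L, seed = 5L)
  fit1 <- train_snn(ds, net, cfg)
  fit2 <- train_snn(ds, net, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$weights, fit2$weights)
  expect_lt(fit1$history$loss[3], fit1$history$loss[1])

  ann1 <- train_ann(ds, tiny_net(ds, bntt = FALSE), cfg)
  ann2 <- train_ann(ds, tiny_net(ds, bntt = FALSE), cfg)
  expect_identical(ann1$weights, ann2$weights)
  expect_lt(ann1$history$loss[3], ann1$history$loss[1])
})

test_that("zero-epoch training returns the (seeded) initialization unchanged", {
  ds <- tiny_dataset()
  net <- tiny_net(ds)
  cfg0 <- train_config(epochs = 0L, timesteps = 6L, seed = 5L)
  fit <- train_snn(ds, net, cfg0)
  ref <- spikesam:::with_seed(5L, init_network(net, seed = NULL))
  expect_identical(fit$weights, ref)
  expect_equal(nrow(fit$history), 0)
  ann <- train_ann(ds, tiny_net(ds, bntt = FALSE), cfg0)
  ref_ann <- spikesam:::with_seed(5L, init_network(tiny_net(ds, bntt = FALSE),
                                                   seed = NULL))
  expect_identical(ann$weights, ref_ann)
})

test_that("conversion sets thresholds to observed maxima, deterministically", {
  ds <- tiny_dataset()
  cfg <- train_config(epochs = 6L, batch_size = 9L, lr = 0.05, seed = 8L)
  ann <- train_ann(ds, tiny_net(ds, bntt = FALSE), cfg)
  calib <- array(ds$images[, , , 1:8], c(1, 12, 12, 8))
  conv1 <- convert_ann_to_snn(ann, calib, timesteps = 24L, seed = 4L)
  conv2 <- convert_ann_to_snn(ann, calib, timesteps = 24L, seed = 4L)
  expect_identical(conv1$report, conv2$report)
  expect_true(all(conv1$report$threshold > 0))
  expect_equal(conv1$report$threshold, conv1$report$max_activation)
  # thresholds equal the recomputed calibration maxima
  raster <- spikesam:::with_seed(4L, spikesam:::poisson_encode_batch(calib, 24L))
  probe <- spikesam:::snn_forward(conv1$config, conv1$weights, raster,
                                  drive_max_layer = 1L)
  expect_equal(conv1$report$threshold[1], probe$drive_max, tolerance = 1e-12)
  # converted layers carry leak 1 and the calibrated threshold
  expect_equal(conv1$config$layers[[1]]$params$leak, 1)
  expect_equal(conv1$config$layers[[1]]$params$threshold,
               conv1$report$threshold[1])
  # zero-activation guard
  dead <- ann
  dead$weights[[1]]$W[] <- -abs(dead$weights[[1]]$W)
  dead$weights[[1]]$W[] <- -1
  expect_error(convert_ann_to_snn(dead, calib, timesteps = 8L, seed = 1L),
               "never activates")
})

test_that("converted firing rates track ReLU activations, better at larger T", {
  ds <- tiny_dataset()
  cfg <- train_config(epochs = 6L, batch_size = 9L, lr = 0.05, seed = 8L)
  ann <- train_ann(ds, tiny_net(ds, bntt = FALSE), cfg)
  calib <- array(ds$images[, , , 1:8], c(1, 12, 12, 8))
  cors <- vapply(c(16L, 256L), function(T) {
    conv <- convert_ann_to_snn(ann, calib, timesteps = T, seed = 4L)
    attr(conv$report, "rate_relu_cor")
  }, numeric(1))
  expect_true(all(cors > 0))
  expect_gt(cors[2], cors[1])
})
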