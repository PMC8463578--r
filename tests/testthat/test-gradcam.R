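test_that("surrogate_grad is the triangular pseudo-derivative", {
  expect_equal(surrogate_grad(1, 1), 1)
  expect_equal(surrogate_grad(c(0, 2, 2.5, -1), 1), c(0, 0, 0, 0))
  d <- runif(5)
  expect_equal(surrogate_grad(1 + d, 1), surrogate_grad(1 - d, 1))
  expect_equal(surrogate_grad(1.25, 1, width = 0.5), 0.5)
  expect_true(all(surrogate_grad(rnorm(20), Inf) == 0))
  expect_error(surrogate_grad(1, 1, width = 0), "width")
})

test_that("snn_gradcam maps are the clamped alpha-weighted activity", {
  cfg <- default_network_config(1, 8, num_classes = 3, timesteps = 6)
  w <- init_network(cfg, seed = 8)
  r <- poisson_encode(matrix(sample(0:255, 64, TRUE), 8, 8), 6, seed = 2)
  g <- snn_gradcam(cfg, w, r, class_label = 2, target_layer = 3)
  alpha <- attr(g, "alpha")
  fw <- forward_network(cfg, w, r, record_layers = 3)
  A <- fw$records[["3"]]
  for (t in 1:6) {
    K <- dim(A)[2]
    expected <- matrix(pmax(0, colSums(matrix(A[t, , , ], nrow = K) * alpha)),
                       dim(A)[3], dim(A)[4])
    expect_equal(matrix(g[t, , ], dim(g)[2], dim(g)[3]), expected,
                 tolerance = 1e-12)
    # zero spike activity at a step -> zero map
    if (all(A[t, , , ] == 0)) expect_true(all(g[t, , ] == 0))
  }
  expect_true(all(g >= 0))  # ReLU clamp
  expect_error(snn_gradcam(cfg, w, r, 9, 3), "class_label")
  expect_error(snn_gradcam(cfg, w, r, 1, 2), "conv")
})

test_that("surrogate BPTT reduces to exact gradients on a linear network", {
  lin <- network_config(list(flatten_layer(), linear_layer(3)), timesteps = 5,
                        num_classes = 3, input_shape = c(1, 4, 4))
  w <- init_network(lin, seed = 3)
  set.seed(14)
  ras <- array(rbinom(5 * 16, 1, 0.4), c(5, 1, 4, 4, 1))
  fwd <- spikesam:::snn_forward(lin, w, ras, keep = TRUE)
  lg <- spikesam:::ce_loss_grad(fwd$potentials, 2L)
  bwd <- spikesam:::snn_backward(lin, w, fwd, lg$dlogits, input_grad = TRUE)
  # exact: dL/dW = dlogits %*% t(sum_t s_t); dL/dx_t = W' dlogits for every t
  s_sum <- rowSums(vapply(1:5, function(t) as.numeric(ras[t, , , , ]),
                          numeric(16)))
  expect_equal(bwd$grads[[2]]$W, lg$dlogits %*% t(s_sum), tolerance = 1e-12)
  expect_equal(as.numeric(bwd$input_grad),
               5 * as.numeric(crossprod(w[[2]]$W, lg$dlogits)),
               tolerance = 1e-12)
})

test_that("ann_gradcam matches its closed forms", {
  cfg <- default_network_config(1, 8, num_classes = 3, timesteps = 2,
                                bntt = FALSE)
  w <- init_network(cfg, seed = 6)
  img <- matrix(sample(0:255, 64, TRUE), 8, 8)
  # zero gradient: output row for the class is all-zero -> zero map
  w0 <- w
  w0[[7]]$W[2, ] <- 0
  expect_true(all(ann_gradcam(cfg, w0, img, 2, 3) == 0))
  # generic map is in [0, 1] after normalization
  G <- ann_gradcam(cfg, w, img, 1, 3)
  expect_true(all(G >= 0 & G <= 1))
  # single channel: map proportional to the activation where positive
  one <- network_config(list(conv_layer(1, 3, neuron_params(1, Inf), bntt = FALSE),
                             gap_layer(), linear_layer(2)),
                        timesteps = 2, num_classes = 2, input_shape = c(1, 6, 6))
  w1 <- init_network(one, seed = 2)
  w1[[3]]$W <- matrix(c(1, -1), 2, 1)  # class 1 logit = +gap, gradient > 0
  fw <- spikesam:::ann_forward(one, w1, array(rep(img[1:6, 1:6] / 255, 1), c(1, 6, 6, 1)),
                               keep = TRUE, record_layers = 1)
  A <- fw$records[["1"]][1, , , 1]
  G1 <- ann_gradcam(one, w1, img[1:6, 1:6], 1, 1)
  if (max(A) > 0) expect_equal(G1, A / max(A), tolerance = 1e-9)
  expect_error(ann_gradcam(cfg, w, img, 7, 3), "class_label")
})

test_that("heatmap_smoothing_probe tabulates per-method, per-layer variance", {
  cfg <- default_network_config(1, 8, num_classes = 3, timesteps = 5)
  w <- init_network(cfg, seed = 11)
  r <- poisson_encode(matrix(sample(0:255, 64, TRUE), 8, 8), 5, seed = 4)
  tab <- heatmap_smoothing_probe(cfg, w, r, class_label = 1, layers = c(1, 3))
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$method, c("sam", "snn_gradcam"))
  expect_setequal(unique(tab$layer), c(1, 3))
  expect_true(all(tab$variance >= 0))
})
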