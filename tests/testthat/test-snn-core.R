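test_that("lif_update reproduces hand-traced soft-reset dynamics", {
  # pure accumulator: infinite threshold, leak 1
  st <- list(potential = 0, last_spike = 0)
  p <- neuron_params(1, Inf)
  pots <- numeric(3)
  for (t in 1:3) {
    r <- lif_update(st, 0.5, p)
    st <- r$state
    pots[t] <- st$potential
    expect_equal(r$spikes, 0)
  }
  expect_equal(pots, c(0.5, 1.0, 1.5))

  # integrate -> fire -> next-step reset, leak 1, theta 1, drive 0.6
  tr <- lif_trace_oracle(rep(0.6, 3), leak = 1, theta = 1)
  st <- list(potential = 0, last_spike = 0)
  p <- neuron_params(1, 1)
  for (t in 1:3) {
    r <- lif_update(st, 0.6, p)
    st <- r$state
    expect_equal(st$potential, tr$potential[t])
    expect_equal(r$spikes, tr$spikes[t])
  }
  expect_equal(tr$potential, c(0.6, 1.2, 0.8))
  expect_equal(tr$spikes, c(0, 1, 0))

  # geometric-series limit: leak 0.5, constant drive 1 -> u converges to 2
  st <- list(potential = 0, last_spike = 0)
  p <- neuron_params(0.5, Inf)
  for (t in 1:60) st <- lif_update(st, 1, p)$state
  expect_equal(st$potential, 2, tolerance = 1e-12)
})

test_that("lif_update validates inputs", {
  p <- neuron_params(1, 1)
  expect_error(lif_update(list(potential = c(0, 0), last_spike = c(0, 0)),
                          1, p), "shape")
  expect_error(lif_update(list(potential = 0, last_spike = 0), NaN, p),
               "non-finite")
  expect_error(neuron_params(1.2, 1), "leak")
  expect_error(neuron_params(0.5, 0), "threshold")
})

test_that("accumulator conserves the drive sum and spiking is monotone in drive", {
  set.seed(31)
  # conservation: leak 1, infinite threshold, potential equals sum of drives
  drives <- matrix(rnorm(25 * 8), 25, 8)
  st <- list(potential = numeric(8), last_spike = numeric(8))
  p <- neuron_params(1, Inf)
  for (t in 1:25) st <- lif_update(st, drives[t, ], p)$state
  expect_equal(st$potential, colSums(drives), tolerance = 1e-12)

  # monotonicity: total spikes non-decreasing in (non-negative) drive level
  counts <- vapply(seq(0, 2, by = 0.1), function(a) {
    sum(lif_trace_oracle(rep(a, 40), leak = 0.9, theta = 1)$spikes)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))

  # spikes are exactly binary under random drives
  tr <- lif_trace_oracle(runif(50, 0, 3), leak = 0.8, theta = 1)
  expect_true(all(tr$spikes %in% c(0, 1)))
})

test_that("bntt_normalize matches closed forms in train and eval mode", {
  prm <- list(gamma = matrix(1, 1, 4), running_mean = matrix(0, 1, 4),
              running_var = matrix(1, 1, 4), eps = 1e-12)
  # identity parameters in eval mode
  x <- matrix(rnorm(6), 1, 6)
  expect_equal(bntt_normalize(x, prm, 2, "eval")$out, x, tolerance = 1e-9)
  # batch {0, 2}: population mean 1, sd 1 -> {-1, +1}
  out <- bntt_normalize(matrix(c(0, 2), 1, 2), prm, 1, "train")$out
  expect_equal(as.numeric(out), c(-1, 1), tolerance = 1e-5)
  # constant batch: eps guard keeps the output finite and zero
  out0 <- bntt_normalize(matrix(3, 1, 5), prm, 1, "train")$out
  expect_true(all(is.finite(out0)))
  expect_equal(as.numeric(out0), rep(0, 5))
  # eval mode is an affine map per (channel, t): f(ax+b) = a f(x) + f(b) - f(0)
  a <- 1.7; b <- 0.3
  f <- function(z) bntt_normalize(z, prm, 3, "eval")$out
  expect_equal(f(a * x + b), a * f(x) + f(matrix(b, 1, 6)) - f(matrix(0, 1, 6)),
               tolerance = 1e-9)
  expect_error(bntt_normalize(x, prm, 9, "eval"), "out of range")
  expect_error(bntt_normalize(matrix(1, 1, 1), prm, 1, "train"), "at least 2")
})

test_that("forward_network: zero input, accumulator closed form, determinism", {
  cfg <- default_network_config(1, 8, num_classes = 3, timesteps = 5, bntt = FALSE)
  w <- init_network(cfg, seed = 4)
  zero <- array(0, c(5, 1, 8, 8))
  fw <- forward_network(cfg, w, zero, record_layers = c(1, 3, 5))
  expect_true(all(vapply(fw$records, function(r) all(r == 0), logical(1))))
  expect_equal(fw$potentials, rep(0, 3))

  # single linear output layer: potentials = sum_t W s_t
  lin <- network_config(list(flatten_layer(), linear_layer(3)),
                        timesteps = 6, num_classes = 3, input_shape = c(1, 4, 4))
  lw <- init_network(lin, seed = 9)
  set.seed(10)
  ras <- array(rbinom(6 * 16, 1, 0.4), c(6, 1, 4, 4))
  fw2 <- forward_network(lin, lw, ras)
  expected <- Reduce(`+`, lapply(1:6, function(t) {
    lw[[2]]$W %*% as.numeric(ras[t, , , ])
  }))
  expect_equal(fw2$potentials, as.numeric(expected), tolerance = 1e-12)

  # determinism: identical weights + raster -> bitwise identical records
  cfg2 <- default_network_config(1, 8, num_classes = 3, timesteps = 5)
  w2 <- init_network(cfg2, seed = 4)
  img <- matrix(sample(0:255, 64, TRUE), 8, 8)
  r <- poisson_encode(img, 5, seed = 3)
  a <- forward_network(cfg2, w2, r, record_layers = 1)
  b <- forward_network(cfg2, w2, r, record_layers = 1)
  expect_identical(a, b)

  expect_error(forward_network(cfg, w, array(0.5, c(5, 1, 8, 8))), "binary")
  expect_error(forward_network(cfg, w, array(0, c(4, 1, 8, 8))), "timesteps")
  expect_error(forward_network(cfg, w, zero, record_layers = 2), "LIF")
})

test_that("network checkpoints round-trip through the array container", {
  cfg <- default_network_config(1, 8, num_classes = 3, timesteps = 4)
  w <- init_network(cfg, seed = 12)
  path <- withr::local_tempfile(fileext = ".bundle")
  save_network(path, cfg, w)
  back <- load_network(path)
  expect_identical(back$weights[[1]]$W, w[[1]]$W)
  expect_identical(back$weights[[1]]$bntt$gamma, w[[1]]$bntt$gamma)
  expect_equal(back$config$timesteps, cfg$timesteps)
  expect_equal(back$config$layers[[1]]$params$threshold, 1)
  expect_equal(back$config$layers[[7]]$params$threshold, Inf)
  # simulations agree after the round trip
  r <- poisson_encode(matrix(128, 8, 8), 4, seed = 1)
  expect_identical(forward_network(cfg, w, r)$potentials,
                   forward_network(back$config, back$weights, r)$potentials)
})
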