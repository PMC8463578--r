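test_that("tscs_kernel evaluates the exponential ISI kernel", {
  expect_equal(tscs_kernel(7, 7, 0.9), 1.0)
  expect_equal(tscs_kernel(5, 3, 0.5), exp(-1))
  expect_equal(tscs_kernel(12, 2, 0), 1.0)
  expect_error(tscs_kernel(5, 3, -0.1), "gamma")
  expect_error(tscs_kernel(3, 5, 0.5), "t_prev")
})

test_that("ncs_step matches the explicit set-based sum", {
  # hand-derived: spikes at steps 1 and 2, evaluated at t = 3, gamma = ln 2
  g <- log(2)
  n <- 0
  train <- c(1, 1, 0)
  for (t in 2:3) n <- ncs_step(n, train[t - 1], g)
  expect_equal(n, 0.25 + 0.5)
  expect_equal(n, ncs_oracle(train, g, 3))

  # flat kernel counts previous spikes
  train2 <- c(1, 1, 0, 1, 0)
  n <- 0
  for (t in 2:5) n <- ncs_step(n, train2[t - 1], 0)
  expect_equal(n, 3)

  # no spikes ever -> zero forever
  n <- 0
  for (t in 2:10) n <- ncs_step(n, 0, 0.4)
  expect_equal(n, 0)

  expect_error(ncs_step(0, 0.5, 0.2), "binary")
  expect_error(ncs_step(0, 1, -1), "gamma")
})

test_that("incremental NCS equals the set-sum oracle on random trains", {
  set.seed(77)
  for (rep in 1:60) {
    T <- sample(4:64, 1)
    gamma <- runif(1, 0, 2)
    train <- rbinom(T, 1, runif(1, 0.1, 0.9))
    n <- 0
    for (t in 2:T) {
      n <- ncs_step(n, train[t - 1], gamma)
      expect_equal(n, ncs_oracle(train, gamma, t), tolerance = 1e-9)
      # bound: tight when every step spikes
      expect_lte(n, sum(exp(-gamma * seq_len(t - 1))) + 1e-12)
    }
  }
})

test_that("gamma limits: spike count at 0, one-step memory at large gamma", {
  set.seed(5)
  train <- rbinom(30, 1, 0.5)
  n0 <- n_big <- 0
  big <- 40
  for (t in 2:30) {
    n0 <- ncs_step(n0, train[t - 1], 0)
    n_big <- ncs_step(n_big, train[t - 1], big)
    expect_equal(n0, sum(train[seq_len(t - 1)]))
    expect_equal(n_big, exp(-big) * train[t - 1], tolerance = 1e-25)
  }
})

test_that("compute_sam matches hand trace and brute-force oracle", {
  # one pixel, one channel, train [1,1,0,1], gamma 0 -> maps [0,1,0,2]
  raster <- array(0, c(4, 1, 1, 1))
  raster[, 1, 1, 1] <- c(1, 1, 0, 1)
  expect_equal(as.numeric(compute_sam(raster, gamma = 0)), c(0, 1, 0, 2))

  # additivity over channels: duplicated channel doubles the map
  r2 <- array(0, c(4, 2, 1, 1))
  r2[, 1, 1, 1] <- r2[, 2, 1, 1] <- c(1, 1, 0, 1)
  expect_equal(unclass(compute_sam(r2, 0.3)),
               2 * unclass(compute_sam(raster, 0.3)))

  # brute-force oracle on random small rasters
  set.seed(21)
  for (rep in 1:5) {
    rr <- array(rbinom(6 * 2 * 3 * 3, 1, 0.5), c(6, 2, 3, 3))
    gamma <- runif(1, 0, 1.5)
    expect_equal(unclass(compute_sam(rr, gamma)), sam_oracle(rr, gamma),
                 tolerance = 1e-9)
  }

  # all-zero raster -> all-zero heatmaps; invalid input rejected
  expect_true(all(compute_sam(array(0, c(3, 1, 2, 2))) == 0))
  expect_error(compute_sam(array(0.5, c(3, 1, 2, 2))), "binary")
  expect_error(compute_sam(matrix(0, 2, 2)), "raster")
})

test_that("compute_sam consumes only the forward record (label-free contract)", {
  expect_false("class_label" %in% names(formals(compute_sam)))
  expect_true("class_label" %in% names(formals(snn_gradcam)))
})

test_that("normalize_heatmaps uses a global max and guards zeros", {
  maps <- array(runif(5 * 4 * 4), c(5, 4, 4))
  maps[3, 2, 2] <- 2
  nm <- normalize_heatmaps(heatmap_sequence(maps))
  expect_equal(max(nm), 1)
  expect_equal(which.max(nm), which.max(maps))  # ordering preserved
  expect_equal(unclass(nm), maps / 2)
  # all-zero guard
  z <- normalize_heatmaps(heatmap_sequence(array(0, c(2, 3, 3))))
  expect_true(all(z == 0))
  # per-time-step variant normalizes each map by its own max
  pt <- normalize_heatmaps(heatmap_sequence(maps), per_timestep = TRUE)
  for (t in 1:5) expect_equal(max(pt[t, , ]), 1)
  expect_error(normalize_heatmaps(array(-1, c(2, 2, 2))), "non-negative")
})

test_that("resize_heatmap is corner-aligned bilinear", {
  m <- matrix(runif(16), 4, 4)
  expect_identical(resize_heatmap(m, 4, 4), m)
  # constant maps stay constant
  expect_equal(resize_heatmap(matrix(0.7, 3, 3), 9, 5),
               matrix(0.7, 9, 5), tolerance = 1e-12)
  # bounds within input range
  up <- resize_heatmap(m, 11, 7)
  expect_gte(min(up), min(m))
  expect_lte(max(up), max(m))
  # single peak lands in the block mapped from the source argmax
  pk <- matrix(0, 4, 4)
  pk[2, 3] <- 1
  up2 <- resize_heatmap(pk, 8, 8)
  am <- which(up2 == max(up2), arr.ind = TRUE)[1, ]
  # corner-aligned: source (2,3) maps to 1 + (2-1)*7/3 = 3.33, 1 + (3-1)*7/3 = 5.67
  expect_true(abs(am["row"] - (1 + 7 / 3)) <= 1)
  expect_true(abs(am["col"] - (1 + 14 / 3)) <= 1)
  expect_error(resize_heatmap(m, 0, 4), ">= 1")
})
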