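# The convolution / pooling / batch-norm kernels against brute-force
# oracles, plus a finite-difference check of the full backward pass.

test_that("conv2d matches the direct-summation oracle on 50 random cases", {
  set.seed(31)
  for (rep in 1:50) {
    H <- sample(2:8, 1)
    C <- sample(1:3, 1)
    F <- sample(1:4, 1)
    x <- array(rnorm(H * H * C), c(H, H, C, 1))
    w <- array(rnorm(9 * C * F), c(3, 3, C, F))
    b <- rnorm(F)
    got <- leukotype:::.conv2d_fwd(x, w, b)
    want <- oracle_conv2d(array(x, c(H, H, C)), w, b)
    expect_lt(max(abs(array(got, c(H, H, F)) - want)), 1e-6)
  }
})

test_that("identity and zero kernels behave as closed forms dictate", {
  x <- array(runif(5 * 5 * 2), c(5, 5, 2, 1))
  w_id <- array(0, c(1, 1, 2, 2))
  w_id[1, 1, 1, 1] <- 1
  w_id[1, 1, 2, 2] <- 1
  y <- leukotype:::.conv2d_fwd(x, w_id, c(0, 0))
  expect_equal(array(y, dim(x)[1:3]), array(x, dim(x)[1:3]), tolerance = 1e-12)
  w0 <- array(0, c(3, 3, 2, 3))
  y0 <- leukotype:::.conv2d_fwd(x, w0, rep(0, 3))
  expect_true(all(y0 == 0))
  # kernel depth mismatch is a shape error
  expect_error(leukotype:::.conv2d_fwd(x, array(0, c(3, 3, 5, 2)), c(0, 0)),
               "depth")
})

test_that("max pooling matches its oracle and halves dimensions", {
  set.seed(32)
  for (rep in 1:20) {
    H <- sample(c(4, 6, 7, 8), 1)
    C <- sample(1:3, 1)
    x <- array(rnorm(H * H * C), c(H, H, C, 1))
    p <- leukotype:::.maxpool_fwd(x)
    expect_equal(array(p$y, c(H %/% 2, H %/% 2, C)),
                 oracle_maxpool(array(x, c(H, H, C))))
  }
})

test_that("upsample is the exact adjoint of its backward pass", {
  set.seed(33)
  x <- array(rnorm(3 * 3 * 2), c(3, 3, 2, 1))
  g <- array(rnorm(6 * 6 * 2), c(6, 6, 2, 1))
  # <up(x), g> == <x, up_bwd(g)>
  expect_equal(sum(leukotype:::.upsample_fwd(x) * g),
               sum(x * leukotype:::.upsample_bwd(g)), tolerance = 1e-10)
})

test_that("batch_normalize matches closed forms and a moment oracle", {
  cst <- array(3, c(4, 4, 2, 5))
  out <- batch_normalize(cst, gamma = c(1, 1), beta = c(5, 5))
  expect_equal(mean(out), 5, tolerance = 1e-6)  # constant channel -> beta

  set.seed(34)
  x <- array(rnorm(6 * 6 * 3 * 10), c(6, 6, 3, 10))
  out2 <- batch_normalize(x, gamma = c(2, 2, 2), beta = c(0, 0, 0))
  for (c in 1:3) {
    expect_equal(mean(out2[, , c, ]), 0, tolerance = 1e-6)
    expect_equal(sd(as.vector(out2[, , c, ])), 2, tolerance = 0.01)
  }
  # against direct per-channel standardization
  for (rep in 1:50) {
    xs <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
    g <- runif(2, 0.5, 2)
    b <- rnorm(2)
    got <- batch_normalize(xs, g, b)
    for (c in 1:2) {
      v <- as.vector(xs[, , c, ])
      sdn <- sqrt(mean((v - mean(v))^2) + 1e-5)
      expect_lt(max(abs(got[, , c, ] - (g[c] * (xs[, , c, ] - mean(v)) / sdn + b[c]))),
                1e-5)
    }
  }
})

test_that("backpropagation through a conv-pool-dense net passes finite differences", {
  set.seed(35)
  layers <- list(
    leukotype:::layer_conv(2L, 3L, 3L, "lrelu"),
    leukotype:::layer_pool(),
    leukotype:::layer_bn(3L),
    leukotype:::layer_flatten(),
    leukotype:::layer_dense(12L, 4L, "relu"),
    leukotype:::layer_dense(4L, 2L, "softmax")
  )
  layers <- leukotype:::init_network(layers, seed = 5)
  x <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  y <- matrix(c(1, 0, 0, 0, 1, 1), 3, 2)  # one-hot rows
  loss_of <- function(ls) {
    out <- leukotype:::nn_forward(ls, x, training = TRUE)$out
    leukotype:::loss_value("cce", out, y)
  }
  fw <- leukotype:::nn_forward(layers, x, training = TRUE)
  grads <- leukotype:::nn_backward(layers, fw$caches, (fw$out - y) / 3,
                                   last_delta_pre = TRUE)
  eps <- 1e-5
  # probe a handful of coordinates in each parameterized layer
  for (li in c(1, 3, 5, 6)) {
    par_name <- if (li == 3) "gamma" else "w"
    grad_name <- if (li == 3) "ggamma" else "gw"
    p <- layers[[li]][[par_name]]
    for (ix in c(1, min(3, length(p)))) {
      lp <- layers; lp[[li]][[par_name]][ix] <- p[ix] + eps
      lm <- layers; lm[[li]][[par_name]][ix] <- p[ix] - eps
      fd <- (loss_of(lp) - loss_of(lm)) / (2 * eps)
      expect_equal(grads[[li]][[grad_name]][ix], fd, tolerance = 1e-4)
    }
  }
})

test_that("dropout is inverted (mean-preserving) in training and off at inference", {
  layers <- list(leukotype:::layer_dropout(0.4))
  x <- array(1, c(8, 8, 4, 16))
  set.seed(36)
  tr <- leukotype:::nn_forward(layers, x, training = TRUE)$out
  expect_equal(mean(tr), 1, tolerance = 0.05)
  expect_true(all(tr %in% c(0, 1 / 0.6)))
  inf <- leukotype:::nn_forward(layers, x, training = FALSE)$out
  expect_identical(inf, x)
})

test_that("training on a tiny regression memorizes and respects epochs = 0", {
  set.seed(37)
  layers <- list(leukotype:::layer_conv(3L, 4L, 3L, "lrelu"),
                 leukotype:::layer_conv(4L, 3L, 3L, "sigmoid"))
  layers <- leukotype:::init_network(layers, seed = 2)
  x <- array(runif(8 * 8 * 3 * 4, 0.3, 0.7), c(8, 8, 3, 4))
  cfg0 <- training_config(epochs = 0, seed = 1)
  res0 <- leukotype:::train_network(layers, x, x, "mse", cfg0)
  expect_identical(res0$layers, layers)
  expect_equal(nrow(res0$history), 0)
  cfg <- training_config(epochs = 30, learning_rate = 0.5, momentum = 0.8,
                         batch_size = 4, seed = 1)
  res <- leukotype:::train_network(layers, x, x, "mse", cfg)
  expect_equal(nrow(res$history), 30)
  expect_lt(res$history$loss[30], res$history$loss[1])
})
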