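test_that("the encoder spec forces the documented shape chain", {
  sp <- dcae_spec()
  expect_equal(sp$latent_grid, c(28L, 28L, 128L))
  expect_equal(dcae_spec(input_size = 56)$latent_grid, c(7L, 7L, 128L))
  expect_error(dcae_spec(input_size = 50), "multiple of 8")
})

test_that("encoding a canonical 224 image yields the 28x28x128 latent", {
  m <- build_dcae(dcae_spec(224), seed = 1)
  img <- image_sample(array(runif(224 * 224 * 3), c(224, 224, 3)))
  z <- encode(m, img)
  expect_equal(dim(z), c(28, 28, 128))
  y <- decode(m, z)
  expect_equal(dim(y), c(224, 224, 3))
  expect_true(min(y) >= 0 && max(y) <= 1)
})

test_that("encoder layer chain halves the grid at each pool", {
  m <- build_dcae(dcae_spec(224), seed = 1)
  img <- array(runif(224 * 224 * 3), c(224, 224, 3, 1))
  x <- img
  dims <- list()
  for (l in m$layers[seq_len(m$n_encoder)]) {
    x <- if (l$type == "conv")
      leukotype:::act_fwd(leukotype:::.conv2d_fwd(x, l$w, l$b), l$act, l$alpha)
    else leukotype:::.maxpool_fwd(x)$y
    dims[[length(dims) + 1]] <- dim(x)[1:3]
  }
  expect_equal(dims[[2]], c(112, 112, 32))
  expect_equal(dims[[4]], c(56, 56, 64))
  expect_equal(dims[[6]], c(28, 28, 128))
})

test_that("initialization is deterministic under the seed", {
  m1 <- build_dcae(dcae_spec(56), seed = 42)
  m2 <- build_dcae(dcae_spec(56), seed = 42)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_dcae(dcae_spec(56), seed = 43)
  expect_false(identical(m1$layers[[1]]$w, m3$layers[[1]]$w))
})

test_that("a zero image with zero biases encodes to a zero latent", {
  m <- build_dcae(dcae_spec(16), seed = 1)  # biases init to zero
  z <- encode(m, image_sample(array(0, c(16, 16, 3))))
  expect_equal(max(abs(z)), 0)
})

test_that("wrong shapes raise shape errors", {
  m <- build_dcae(dcae_spec(56), seed = 1)
  expect_error(encode(m, array(0.1, c(48, 48, 3))), "56x56x3")
  expect_error(decode(m, array(0, c(9, 9, 128))), "7x7x128")
})

test_that("a toy encoder matches the composed conv + pool oracle", {
  set.seed(41)
  layers <- leukotype:::init_network(
    list(leukotype:::layer_conv(3L, 4L, 3L, "lrelu"),
         leukotype:::layer_pool()), seed = 9)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3, 1))
  got <- leukotype:::nn_forward(layers, x)$out
  z <- oracle_conv2d(array(x, c(8, 8, 3)), layers[[1]]$w, layers[[1]]$b)
  z <- ifelse(z > 0, z, 0.3 * z)  # leaky rectifier
  want <- oracle_maxpool(z)
  expect_lt(max(abs(array(got, c(4, 4, 4)) - want)), 1e-6)
})

test_that("a toy decoder matches the upsample + conv oracle", {
  layers <- leukotype:::init_network(
    list(leukotype:::layer_upsample(),
         leukotype:::layer_conv(2L, 3L, 3L, "sigmoid")), seed = 10)
  z <- array(runif(3 * 3 * 2), c(3, 3, 2, 1))
  got <- leukotype:::nn_forward(layers, z)$out
  z3 <- array(z, c(3, 3, 2))
  up <- array(0, c(6, 6, 2))
  for (c in 1:2) for (i in 1:6) for (j in 1:6)
    up[i, j, c] <- z3[ceiling(i / 2), ceiling(j / 2), c]
  want <- 1 / (1 + exp(-oracle_conv2d(up, layers[[2]]$w, layers[[2]]$b)))
  expect_lt(max(abs(array(got, c(6, 6, 3)) - want)), 1e-6)
})

test_that("training memorizes a constant image to below 1e-3", {
  img <- image_sample(array(0.6, c(16, 16, 3)))
  m <- build_dcae(dcae_spec(16), seed = 3)
  m <- train_dcae(m, list(img), training_config(epochs = 150,
                                                learning_rate = 0.05,
                                                batch_size = 1, seed = 4))
  expect_lt(reconstruction_mse(m, list(img)), 1e-3)
})

test_that("training loss is mostly non-increasing on a small synthetic set", {
  imgs <- generate_class_images(default_cell_specs()$erythroblast, 50,
                                image_size = 16, seed = 21)
  m <- build_dcae(dcae_spec(16), seed = 5)
  m <- train_dcae(m, imgs, training_config(epochs = 30, learning_rate = 0.02,
                                           seed = 6))
  expect_equal(nrow(m$history), 30)
  steps <- diff(m$history$loss)
  expect_gte(mean(steps <= 0), 0.8)
  expect_lte(m$history$loss[30], m$history$loss[1])
})

test_that("epochs = 0 leaves parameters untouched with empty history", {
  m <- build_dcae(dcae_spec(16), seed = 7)
  m2 <- train_dcae(m, list(image_sample(array(0.5, c(16, 16, 3)))),
                   training_config(epochs = 0))
  expect_identical(m2$layers, m$layers)
  expect_equal(nrow(m2$history), 0)
  expect_false(m2$trained)
})

test_that("reconstruction error agrees with its closed forms", {
  x <- array(runif(4 * 4 * 3), c(4, 4, 3, 1))
  expect_equal(leukotype:::mse_between(x, x), 0)
  expect_equal(leukotype:::mse_between(x, x + 0.1), 0.01, tolerance = 1e-12)
})

test_that("synthesize returns the contracted count with labels preserved", {
  imgs <- generate_class_images(default_cell_specs()$myeloblast, 4,
                                image_size = 16, seed = 31)
  m <- build_dcae(dcae_spec(16), seed = 8)
  out <- synthesize(m, imgs, 7, plan = gt_plan(seed = 1), seed = 2)
  expect_length(out, 7)
  expect_true(all(vapply(out, image_label, character(1)) == "myeloblast"))
  # outputs differ from their sources (the autoencoder is lossy)
  d <- mean(abs(unclass(out[[1]]) - unclass(imgs[[1]])))
  expect_gt(d, 0)
  out2 <- synthesize(m, imgs, 7, plan = gt_plan(seed = 1), seed = 2)
  for (i in 1:7) expect_identical(unclass(out[[i]]), unclass(out2[[i]]))
  expect_error(synthesize(m, imgs, 0), ">= 1")
  expect_error(synthesize(m, list(), 3), "empty")
})

test_that("checkpoints round-trip models through disk", {
  dir <- withr::local_tempdir()
  m <- build_dcae(dcae_spec(16), seed = 11)
  f <- file.path(dir, "dcae.rds")
  save_model(m, f)
  m2 <- load_model(f)
  img <- image_sample(array(runif(16 * 16 * 3), c(16, 16, 3)))
  expect_identical(encode(m2, img), encode(m, img))
  expect_error(load_model(file.path(dir, "none.rds")), "not found")
})
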