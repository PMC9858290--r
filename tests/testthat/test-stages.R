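# Toy latent grids keep these fast: the 7x7x<C> grid is the 56-pixel
# variant of the canonical 28x28x128 input.

blob_latents <- function(n_per, centers, grid = c(7, 7, 8), seed = 1) {
  set.seed(seed)
  k <- length(centers)
  z <- array(rnorm(prod(grid) * n_per * k, sd = 0.3),
             c(grid, n_per * k))
  for (i in seq_len(k)) {
    idx <- (i - 1) * n_per + seq_len(n_per)
    z[, , , idx] <- z[, , , idx] + centers[[i]]
  }
  z
}

test_that("stage I default spec produces the forced 12544-unit flatten", {
  sp <- stage1_spec()
  expect_equal(sp$flat_units, 7 * 7 * 256)
  sp2 <- stage1_spec(input_grid = c(7, 7, 128))
  expect_equal(sp2$flat_units, 1 * 1 * 256)
  expect_error(stage1_spec(dropout_rate = 1), "\\[0, 1\\)")
})

test_that("stage II default spec ends in a 7x7x256 grid and 50-8 head", {
  sp <- stage2_spec()
  expect_equal(sp$flat_units, 7 * 7 * 256)
  m <- build_stage2(stage2_spec(input_grid = c(7, 7, 16),
                                conv_filters = c(4, 4, 8, 8)), seed = 1)
  dense <- Filter(function(l) l$type == "dense", m$layers)
  expect_equal(dense[[1]]$out_units, 50)
  expect_equal(dense[[2]]$out_units, 8)
})

test_that("builders are deterministic under the seed", {
  a <- build_stage1(stage1_spec(input_grid = c(7, 7, 8),
                                conv_filters = c(4, 8, 8)), seed = 9)
  b <- build_stage1(stage1_spec(input_grid = c(7, 7, 8),
                                conv_filters = c(4, 8, 8)), seed = 9)
  expect_identical(a$layers, b$layers)
})

test_that("stage I learns linearly separable blobs to >= 0.99 accuracy", {
  z <- blob_latents(20, list(-0.5, 0.5), grid = c(7, 7, 8), seed = 2)
  labels <- rep(c(0, 1), each = 20)
  m <- build_stage1(stage1_spec(input_grid = c(7, 7, 8),
                                conv_filters = c(4, 8, 8), l2 = 0), seed = 3)
  m <- train_stage1(m, z, labels,
                    training_config(epochs = 30, learning_rate = 0.05,
                                    batch_size = 8, seed = 4))
  expect_equal(nrow(m$history), 30)
  p <- predict_typicality(m, z)
  expect_gte(mean((p > 0.5) == (labels == 1)), 0.99)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("stage I refuses single-class training and respects epochs = 0", {
  z <- blob_latents(4, list(0), grid = c(7, 7, 4), seed = 5)
  expect_error(train_stage1(build_stage1(stage1_spec(c(7, 7, 4),
                                                     c(4, 4, 4)), 1),
                            z, rep(1, 4), training_config(epochs = 1)),
               "both typical and atypical")
  m <- build_stage1(stage1_spec(c(7, 7, 4), c(4, 4, 4)), seed = 1)
  m0 <- train_stage1(m, z, c(0, 1, 0, 1), training_config(epochs = 0))
  expect_identical(m0$layers, m$layers)
})

test_that("inference is deterministic and batch-size invariant", {
  z <- blob_latents(6, list(-0.5, 0.5), grid = c(7, 7, 4), seed = 6)
  m <- build_stage1(stage1_spec(c(7, 7, 4), c(4, 4, 4)), seed = 2)
  m <- train_stage1(m, z, rep(c(0, 1), each = 6),
                    training_config(epochs = 3, learning_rate = 0.01, seed = 3))
  single <- predict_typicality(m, array(z[, , , 1], c(7, 7, 4)))
  batched <- predict_typicality(m, z)
  expect_equal(single, batched[1], tolerance = 1e-5)
  expect_identical(predict_typicality(m, z), predict_typicality(m, z))
})

test_that("stage II probability vectors are valid and canonical", {
  m <- build_stage2(stage2_spec(c(7, 7, 4), c(4, 4, 8, 8)), seed = 4)
  z <- blob_latents(3, list(0), grid = c(7, 7, 4), seed = 7)
  p <- predict_subtype(m, z)
  expect_equal(dim(p), c(3, 8))
  expect_equal(colnames(p), atypical_classes())
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  p1 <- predict_subtype(m, array(z[, , , 1], c(7, 7, 4)))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_identical(p1, predict_subtype(m, array(z[, , , 1], c(7, 7, 4))))
})

test_that("softmax output sums to one across many random draws", {
  set.seed(8)
  for (rep in 1:25) {
    m <- build_stage2(stage2_spec(c(7, 7, 2), c(2, 2, 4, 4)),
                      seed = sample.int(1e6, 1))
    z <- array(rnorm(7 * 7 * 2 * 2, sd = 2), c(7, 7, 2, 2))
    expect_equal(rowSums(predict_subtype(m, z)), c(1, 1), tolerance = 1e-6)
  }
})

test_that("argmax uses canonical order with lowest-index tie-break", {
  expect_equal(argmax_class(c(0, 0, 0, 0, 1, 0, 0, 0)), "myeloblast")
  expect_equal(argmax_class(rep(1 / 8, 8)), "erythroblast")
  pi <- setNames(rep(0, 8), atypical_classes())
  pi["myeloblast"] <- 0.99
  pi["promyelocyte"] <- 0.01
  expect_equal(argmax_class(pi), "myeloblast")
  m <- matrix(1 / 8, 2, 8)
  m[2, 4] <- 0.9
  expect_equal(argmax_class(m), c("erythroblast", "monoblast"))
})

test_that("stage II learns separable clusters and validates labels", {
  classes <- atypical_classes()
  centers <- as.list(seq(-0.7, 0.7, length.out = 8))
  z <- blob_latents(8, centers, grid = c(7, 7, 4), seed = 9)
  labels <- rep(classes, each = 8)
  m <- build_stage2(stage2_spec(c(7, 7, 4), c(4, 8, 8, 8), l2 = 0), seed = 5)
  m <- train_stage2(m, z, labels,
                    training_config(epochs = 60, learning_rate = 0.05,
                                    batch_size = 16, seed = 6))
  pred <- argmax_class(predict_subtype(m, z))
  expect_gte(mean(pred == labels), 0.95)
  expect_equal(nrow(m$history), 60)

  expect_error(train_stage2(m, z, rep("monocyte", 64),
                            training_config(epochs = 1)), "unknown")
  expect_error(train_stage2(m, z, rep("myeloblast", 64),
                            training_config(epochs = 1)), "two subtypes")
})

test_that("with zero L2 and dropout the spec reduces to the plain CNN", {
  sp <- stage1_spec(input_grid = c(7, 7, 4), conv_filters = c(4, 4, 4),
                    dropout_rate = 0, l2 = 0)
  m <- build_stage1(sp, seed = 3)
  z <- blob_latents(4, list(-0.5, 0.5), grid = c(7, 7, 4), seed = 10)
  # training-mode forward without dropout is deterministic like inference
  set.seed(1)
  a <- leukotype:::nn_forward(m$layers, z, training = TRUE)$out
  set.seed(2)
  b <- leukotype:::nn_forward(m$layers, z, training = TRUE)$out
  expect_identical(a, b)
})
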