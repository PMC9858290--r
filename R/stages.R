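#' Stage I specification: typical vs atypical gate
#'
#' A CNN operating on the autoencoder's latent representation. Three
#' batch-normalized 3x3 convolutions (64, 128, 256 filters, rectifier
#' activation, L2 weight decay), max-pooling after the first two, 20%
#' dropout throughout, a 50-unit dense layer and a single sigmoid output
#' giving the probability that the cell is atypical.
#'
#' @param input_grid latent grid `(h, w, channels)`; default
#'   `c(28, 28, 128)` (the canonical latent), `c(7, 7, 128)` for the
#'   56-pixel desk-scale variant.
#' @param conv_filters three filter counts (default 64, 128, 256).
#' @param dense_units width of the dense head (default 50).
#' @param dropout_rate dropout probability in `[0, 1)` (default 0.2).
#' @param l2 L2 weight-decay coefficient (default 1e-4; set 0 for the
#'   unregularized ablation).
#' @param kernel convolution kernel edge (default 3).
#' @return a `stage1_spec` list.
#' @export
stage1_spec <- function(input_grid = c(28L, 28L, 128L),
                        conv_filters = c(64L, 128L, 256L),
                        dense_units = 50L, dropout_rate = 0.2,
                        l2 = 1e-4, kernel = 3L) {
  if (!(dropout_rate >= 0 && dropout_rate < 1))
    abort("dropout_rate must be in [0, 1)")
  if (length(conv_filters) != 3) abort("stage I uses three conv layers")
  g <- as.integer(input_grid)
  flat <- (g[1] %/% 2L %/% 2L)^2 * conv_filters[3]
  if (flat < 1) abort("input grid too small for two pooling stages")
  structure(list(input_grid = g, conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate, l2 = l2,
                 kernel = as.integer(kernel), flat_units = as.integer(flat)),
            class = "stage1_spec")
}

#' Stage II specification: eight-way atypical subtype model
#'
#' Four batch-normalized 3x3 convolutions (32, 64, 128, 256 filters) with
#' max-pooling after the third and fourth, 20% dropout, a 50-unit dense
#' layer and an 8-unit softmax output over the atypical subtypes in
#' canonical (alphabetical) order.
#'
#' @inheritParams stage1_spec
#' @param conv_filters four filter counts (default 32, 64, 128, 256).
#' @return a `stage2_spec` list.
#' @export
stage2_spec <- function(input_grid = c(28L, 28L, 128L),
                        conv_filters = c(32L, 64L, 128L, 256L),
                        dense_units = 50L, dropout_rate = 0.2,
                        l2 = 1e-4, kernel = 3L) {
  if (!(dropout_rate >= 0 && dropout_rate < 1))
    abort("dropout_rate must be in [0, 1)")
  if (length(conv_filters) != 4) abort("stage II uses four conv layers")
  g <- as.integer(input_grid)
  flat <- (g[1] %/% 2L %/% 2L)^2 * conv_filters[4]
  if (flat < 1) abort("input grid too small for two pooling stages")
  structure(list(input_grid = g, conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate, l2 = l2,
                 kernel = as.integer(kernel), flat_units = as.integer(flat)),
            class = "stage2_spec")
}

#' Build the stage classifiers
#'
#' Parameter initialization is deterministic under the seed. The layer
#' chains follow the specs: stage I pools after convolutions 1 and 2,
#' stage II after convolutions 3 and 4; both end in a 50-unit dense layer
#' and dropout before the output unit(s).
#'
#' @param spec a [stage1_spec()] or [stage2_spec()].
#' @param seed integer seed.
#' @return a `stage1_model` / `stage2_model` object.
#' @export
build_stage1 <- function(spec = stage1_spec(), seed = 1L) {
  f <- spec$conv_filters
  k <- spec$kernel
  r <- spec$dropout_rate
  layers <- list(
    layer_conv(spec$input_grid[3], f[1], k, "relu"), layer_bn(f[1]),
    layer_pool(), layer_dropout(r),
    layer_conv(f[1], f[2], k, "relu"), layer_bn(f[2]),
    layer_pool(), layer_dropout(r),
    layer_conv(f[2], f[3], k, "relu"), layer_bn(f[3]), layer_dropout(r),
    layer_flatten(),
    layer_dense(spec$flat_units, spec$dense_units, "relu"), layer_dropout(r),
    layer_dense(spec$dense_units, 1L, "sigmoid")
  )
  structure(list(spec = spec, layers = init_network(layers, seed),
                 seed = as.integer(seed), trained = FALSE, history = NULL),
            class = "stage1_model")
}

#' @rdname build_stage1
#' @export
build_stage2 <- function(spec = stage2_spec(), seed = 1L) {
  f <- spec$conv_filters
  k <- spec$kernel
  r <- spec$dropout_rate
  layers <- list(
    layer_conv(spec$input_grid[3], f[1], k, "relu"), layer_bn(f[1]),
    layer_conv(f[1], f[2], k, "relu"), layer_bn(f[2]),
    layer_conv(f[2], f[3], k, "relu"), layer_bn(f[3]),
    layer_pool(), layer_dropout(r),
    layer_conv(f[3], f[4], k, "relu"), layer_bn(f[4]),
    layer_pool(), layer_dropout(r),
    layer_flatten(),
    layer_dense(spec$flat_units, spec$dense_units, "relu"), layer_dropout(r),
    layer_dense(spec$dense_units, 8L, "softmax")
  )
  structure(list(spec = spec, layers = init_network(layers, seed),
                 seed = as.integer(seed), trained = FALSE, history = NULL),
            class = "stage2_model")
}

as_latent_batch <- function(z, grid) {
  single <- length(dim(z)) == 3
  if (single) z <- array(z, c(dim(z), 1L))
  if (length(dim(z)) != 4 || !all(dim(z)[1:3] == grid))
    abort(sprintf("latent input must be %s, got %s",
                  paste(grid, collapse = "x"),
                  paste(dim(z), collapse = "x")))
  list(x = z, single = single)
}

#' Train the stage I gate
#'
#' @param model a `stage1_model`.
#' @param z latent batch (`h x w x c x n`).
#' @param labels per-sample class labels (mapped to typical/atypical via
#'   the taxonomy), or a logical/0-1 vector where `TRUE`/1 = atypical.
#' @param cfg a [training_config()]; the loss is binary cross-entropy and
#'   the spec's L2 coefficient is applied to the weights.
#' @param taxonomy taxonomy used to map labels to groups.
#' @return the fitted model with a `history` tibble (per-epoch training
#'   and, when `validation_split > 0`, validation loss/accuracy).
#' @export
train_stage1 <- function(model, z, labels, cfg = training_config(),
                         taxonomy = wbc_taxonomy()) {
  zb <- as_latent_batch(z, model$spec$input_grid)
  y <- if (is.character(labels) || is.factor(labels))
    as.numeric(class_group(as.character(labels), taxonomy) == "atypical")
  else as.numeric(labels)
  if (length(y) != dim(zb$x)[4])
    abort("labels must match the number of latent samples")
  if (length(unique(y)) < 2)
    abort("stage I training needs both typical and atypical examples")
  cfg$l2 <- model$spec$l2
  res <- train_network(model$layers, zb$x, y, "bce", cfg)
  model$layers <- res$layers
  model$history <- res$history
  model$trained <- cfg$epochs > 0 || isTRUE(model$trained)
  model
}

#' Probability that a cell is atypical
#'
#' Inference mode: dropout disabled, batch-norm running statistics, so a
#' sample's prediction does not depend on what else is in the batch.
#'
#' @param model a trained `stage1_model`.
#' @param z one latent (`h x w x c`) or a batch (`... x n`).
#' @param batch_size inference chunk size.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_typicality <- function(model, z, batch_size = 32L) {
  zb <- as_latent_batch(z, model$spec$input_grid)
  as.numeric(nn_predict(model$layers, zb$x, batch_size))
}

#' Train the stage II subtype model
#'
#' @param model a `stage2_model`.
#' @param z latent batch.
#' @param labels per-sample atypical class labels (all must belong to the
#'   eight-class atypical set; at least two classes present).
#' @param cfg a [training_config()]; categorical cross-entropy loss.
#' @return the fitted model with `history`.
#' @export
train_stage2 <- function(model, z, labels, cfg = training_config()) {
  zb <- as_latent_batch(z, model$spec$input_grid)
  labels <- as.character(labels)
  check_labels(labels, atypical_classes(), "stage II training labels")
  if (length(labels) != dim(zb$x)[4])
    abort("labels must match the number of latent samples")
  if (length(unique(labels)) < 2)
    abort("stage II training needs at least two subtypes")
  classes <- atypical_classes()
  y <- matrix(0, length(labels), length(classes))
  y[cbind(seq_along(labels), match(labels, classes))] <- 1
  cfg$l2 <- model$spec$l2
  res <- train_network(model$layers, zb$x, y, "cce", cfg)
  model$layers <- res$layers
  model$history <- res$history
  model$trained <- cfg$epochs > 0 || isTRUE(model$trained)
  model
}

#' Subtype probability vectors
#'
#' Returns the eight-way softmax output over the atypical subtypes in
#' canonical (alphabetical) order; each row sums to 1.
#'
#' @param model a trained `stage2_model`.
#' @param z one latent or a batch.
#' @param batch_size inference chunk size.
#' @return for a single latent, a named numeric vector of 8
#'   probabilities; for a batch, an `n x 8` matrix with class-name
#'   columns.
#' @export
predict_subtype <- function(model, z, batch_size = 32L) {
  zb <- as_latent_batch(z, model$spec$input_grid)
  p <- nn_predict(model$layers, zb$x, batch_size)
  colnames(p) <- atypical_classes()
  if (zb$single) p[1, ] else p
}

#' Pick the predicted class from a probability vector
#'
#' Ties are broken toward the lowest canonical index (alphabetically
#' first class).
#'
#' @param pi a probability vector over the 8 atypical classes (named or
#'   in canonical order), or an `n x 8` matrix.
#' @return character label(s).
#' @examples
#' argmax_class(c(0, 0, 0, 0, 1, 0, 0, 0))  # "myeloblast"
#' argmax_class(rep(1 / 8, 8))              # tie -> "erythroblast"
#' @export
argmax_class <- function(pi) {
  if (is.matrix(pi)) {
    atypical_classes()[max.col(pi, ties.method = "first")]
  } else {
    if (length(pi) != 8) abort("probability vector must have 8 entries")
    atypical_classes()[which.max(pi)]
  }
}

#' @export
print.stage1_model <- function(x, ...) {
  cat(sprintf("<stage1 typical-vs-atypical CNN, input %s%s>\n",
              paste(x$spec$input_grid, collapse = "x"),
              if (x$trained) ", trained" else ""))
  invisible(x)
}

#' @export
print.stage2_model <- function(x, ...) {
  cat(sprintf("<stage2 atypical-subtype CNN, input %s%s>\n",
              paste(x$spec$input_grid, collapse = "x"),
              if (x$trained) ", trained" else ""))
  invisible(x)
}

#' @export
tidy.stage1_model <- function(x, ...) x$history %||% tibble()

#' @export
tidy.stage2_model <- function(x, ...) x$history %||% tibble()

#' @export
glance.stage1_model <- function(x, ...) {
  h <- x$history
  tibble(trained = x$trained,
         epochs = if (is.null(h)) 0L else nrow(h),
         final_loss = if (is.null(h) || nrow(h) == 0) NA_real_
                      else h$loss[nrow(h)],
         final_accuracy = if (is.null(h) || nrow(h) == 0) NA_real_
                          else h$accuracy[nrow(h)])
}

#' @export
glance.stage2_model <- function(x, ...) glance.stage1_model(x, ...)
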