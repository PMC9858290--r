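# Minimal sequential network framework backing the autoencoder and the
# two stage classifiers. Feature stacks are H x W x C x N arrays; after a
# flatten layer, activations are N x D matrices. Convolution, pooling and
# upsampling run in compiled code; everything else is vectorized R.

layer_conv <- function(in_ch, out_ch, kernel = 3L,
                       act = c("lrelu", "relu", "sigmoid", "linear"),
                       alpha = 0.3) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       act = match.arg(act), alpha = alpha, w = NULL, b = NULL)
}
layer_pool <- function() list(type = "pool")
layer_upsample <- function() list(type = "upsample")
layer_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", channels = channels, momentum = momentum, eps = eps,
       gamma = rep(1, channels), beta = rep(0, channels),
       rmean = rep(0, channels), rvar = rep(1, channels))
}
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_flatten <- function() list(type = "flatten")
layer_dense <- function(in_units, out_units,
                        act = c("relu", "sigmoid", "softmax", "linear")) {
  list(type = "dense", in_units = in_units, out_units = out_units,
       act = match.arg(act), w = NULL, b = NULL)
}

# He initialization for rectifier layers, Glorot otherwise.
init_network <- function(layers, seed) {
  with_seed(seed, {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type == "conv") {
        fan_in <- l$kernel^2 * l$in_ch
        sd <- if (l$act %in% c("relu", "lrelu")) sqrt(2 / fan_in)
              else sqrt(2 / (fan_in + l$kernel^2 * l$out_ch))
        layers[[i]]$w <- array(rnorm(l$kernel^2 * l$in_ch * l$out_ch, 0, sd),
                               c(l$kernel, l$kernel, l$in_ch, l$out_ch))
        layers[[i]]$b <- rep(0, l$out_ch)
      } else if (l$type == "dense") {
        sd <- if (l$act == "relu") sqrt(2 / l$in_units)
              else sqrt(2 / (l$in_units + l$out_units))
        layers[[i]]$w <- matrix(rnorm(l$in_units * l$out_units, 0, sd),
                                l$in_units, l$out_units)
        layers[[i]]$b <- rep(0, l$out_units)
      }
    }
  })
  layers
}

act_fwd <- function(z, act, alpha = 0.3) {
  switch(act,
    linear = z,
    relu = pmax(z, 0),
    lrelu = ifelse(z > 0, z, alpha * z),
    sigmoid = 1 / (1 + exp(-z)),
    softmax = {
      m <- apply(z, 1, max)
      e <- exp(z - m)
      e / rowSums(e)
    }
  )
}

# gradient through the activation given upstream grad g (wrt y), the
# pre-activation z and the activation output y
act_bwd <- function(g, z, y, act, alpha = 0.3) {
  switch(act,
    linear = g,
    relu = g * (z > 0),
    lrelu = g * ifelse(z > 0, 1, alpha),
    sigmoid = g * y * (1 - y),
    softmax = abort("softmax gradients must use the fused loss path")
  )
}

# per-channel moments of an H x W x C x N stack, plus the permuted matrix
# used by batch-norm (rows = H*W*N, cols = C)
channel_matrix <- function(x) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  xm
}
unchannel_matrix <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1, 2, 4, 3))
}

#' Batch-normalize a feature stack
#'
#' Normalizes each channel to zero mean and unit variance (training mode:
#' batch statistics; inference mode: running statistics), then applies the
#' learned per-channel scale and shift. Zero-variance channels are
#' stabilized by the epsilon term rather than raising an error.
#'
#' @param x `H x W x C x N` array (a batch of feature stacks).
#' @param gamma,beta per-channel scale and shift.
#' @param eps numerical stabilizer added to the variance.
#' @return array of the same shape.
#' @export
batch_normalize <- function(x, gamma = rep(1, dim(x)[3]),
                            beta = rep(0, dim(x)[3]), eps = 1e-5) {
  d <- dim(x)
  xm <- channel_matrix(x)
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  xhat <- sweep(sweep(xm, 2, mu), 2, sqrt(v + eps), "/")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  unchannel_matrix(out, d)
}

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      z <- .conv2d_fwd(x, l$w, l$b)
      y <- act_fwd(z, l$act, l$alpha)
      caches[[i]] <- list(x = x, z = z, y = y)
      x <- y
    } else if (l$type == "pool") {
      p <- .maxpool_fwd(x)
      caches[[i]] <- list(idx = p$idx, in_dim = dim(x))
      x <- p$y
    } else if (l$type == "upsample") {
      caches[[i]] <- list()
      x <- .upsample_fwd(x)
    } else if (l$type == "bn") {
      d <- dim(x)
      xm <- channel_matrix(x)
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
      } else {
        mu <- l$rmean
        v <- l$rvar
      }
      invstd <- 1 / sqrt(v + l$eps)
      xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
      out <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
      caches[[i]] <- list(xhat = xhat, invstd = invstd, d = d,
                          mu = if (training) mu, v = if (training) v)
      x <- unchannel_matrix(out, d)
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        keep <- 1 - l$rate
        mask <- array((runif(length(x)) < keep) / keep, dim(x) %||% length(x))
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      } else caches[[i]] <- list(mask = NULL)
    } else if (l$type == "flatten") {
      d <- dim(x)
      caches[[i]] <- list(in_dim = d)
      x <- t(matrix(x, prod(d[1:3]), d[4]))
    } else if (l$type == "dense") {
      z <- sweep(x %*% l$w, 2, l$b, "+")
      y <- act_fwd(z, l$act)
      caches[[i]] <- list(x = x, z = z, y = y)
      x <- y
    }
  }
  list(out = x, caches = caches)
}

# Backward pass. `grad` is the gradient wrt the network output; when
# `last_delta_pre` is TRUE it is instead the gradient wrt the last dense
# layer's pre-activation (the fused cross-entropy path).
nn_backward <- function(layers, caches, grad, last_delta_pre = FALSE) {
  grads <- vector("list", length(layers))
  g <- grad
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cc <- caches[[i]]
    if (l$type == "conv") {
      gz <- act_bwd(g, cc$z, cc$y, l$act, l$alpha)
      bw <- .conv2d_bwd(cc$x, l$w, gz, i > 1)
      grads[[i]] <- list(gw = bw$gw, gb = bw$gb)
      g <- if (i > 1) bw$gx else NULL
    } else if (l$type == "pool") {
      g <- .maxpool_bwd(g, cc$idx, cc$in_dim)
    } else if (l$type == "upsample") {
      g <- .upsample_bwd(g)
    } else if (l$type == "bn") {
      gm <- channel_matrix(g)
      n <- nrow(gm)
      ggamma <- colSums(gm * cc$xhat)
      gbeta <- colSums(gm)
      gxhat <- sweep(gm, 2, l$gamma, "*")
      # d/dx of (x - mu) / sd with batch statistics:
      #   invstd * (gxhat - mean(gxhat) - xhat * mean(gxhat * xhat))
      centered <- sweep(gxhat, 2, colMeans(gxhat))
      proj <- sweep(cc$xhat, 2, colMeans(gxhat * cc$xhat), "*")
      gx <- sweep(centered - proj, 2, cc$invstd, "*")
      grads[[i]] <- list(ggamma = ggamma, gbeta = gbeta)
      g <- unchannel_matrix(gx, cc$d)
    } else if (l$type == "dropout") {
      if (!is.null(cc$mask)) g <- g * cc$mask
    } else if (l$type == "flatten") {
      g <- array(t(g), cc$in_dim)
    } else if (l$type == "dense") {
      gz <- if (i == length(layers) && last_delta_pre) g
            else act_bwd(g, cc$z, cc$y, l$act)
      grads[[i]] <- list(gw = crossprod(cc$x, gz), gb = colSums(gz))
      g <- if (i > 1) tcrossprod(gz, l$w) else NULL
    }
  }
  grads
}

# update running batch-norm statistics after a training-mode forward pass
bn_update_running <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bn" && !is.null(caches[[i]]$mu)) {
      m <- layers[[i]]$momentum
      layers[[i]]$rmean <- (1 - m) * layers[[i]]$rmean + m * caches[[i]]$mu
      layers[[i]]$rvar <- (1 - m) * layers[[i]]$rvar + m * caches[[i]]$v
    }
  }
  layers
}

new_sgd_state <- function(layers) {
  lapply(layers, function(l) {
    if (l$type %in% c("conv", "dense"))
      list(vw = array(0, dim(l$w) %||% c(nrow(l$w), ncol(l$w))),
           vb = rep(0, length(l$b)))
    else if (l$type == "bn")
      list(vgamma = rep(0, l$channels), vbeta = rep(0, l$channels))
    else NULL
  })
}

sgd_step <- function(layers, state, grads, lr, momentum, l2 = 0) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type %in% c("conv", "dense")) {
      gw <- grads[[i]]$gw
      if (l2 > 0) gw <- gw + l2 * l$w
      state[[i]]$vw <- momentum * state[[i]]$vw - lr * gw
      state[[i]]$vb <- momentum * state[[i]]$vb - lr * grads[[i]]$gb
      layers[[i]]$w <- l$w + state[[i]]$vw
      layers[[i]]$b <- l$b + state[[i]]$vb
    } else if (l$type == "bn") {
      state[[i]]$vgamma <- momentum * state[[i]]$vgamma - lr * grads[[i]]$ggamma
      state[[i]]$vbeta <- momentum * state[[i]]$vbeta - lr * grads[[i]]$gbeta
      layers[[i]]$gamma <- l$gamma + state[[i]]$vgamma
      layers[[i]]$beta <- l$beta + state[[i]]$vbeta
    }
  }
  list(layers = layers, state = state)
}

loss_value <- function(loss, out, target) {
  eps <- 1e-12
  switch(loss,
    mse = mean((out - target)^2),
    bce = -mean(target * log(out + eps) + (1 - target) * log(1 - out + eps)),
    cce = -mean(rowSums(target * log(out + eps)))
  )
}

#' Training configuration
#'
#' Optimizer settings shared by the autoencoder and the classifiers:
#' stochastic gradient descent with momentum. Defaults follow the training
#' protocol the models were designed with (momentum 0.8, learning rate
#' 1e-5); scaled-down experiments on small synthetic images use a larger
#' learning rate, since with a mean-squared loss the gradient magnitude
#' shrinks with problem size.
#'
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size (default 32).
#' @param learning_rate SGD learning rate (> 0).
#' @param momentum SGD momentum in `[0, 1)` (default 0.8).
#' @param l2 L2 weight-decay coefficient (applied to conv/dense weights).
#' @param seed integer seed controlling shuffling, dropout and weight
#'   initialization where applicable.
#' @param validation_split fraction of the training data held out for the
#'   per-epoch validation metrics (0 disables).
#' @param verbose print a line per epoch.
#' @return a `training_config` list.
#' @export
training_config <- function(epochs = 100L, batch_size = 32L,
                            learning_rate = 1e-5, momentum = 0.8,
                            l2 = 0, seed = 1L, validation_split = 0,
                            verbose = FALSE) {
  if (!(momentum >= 0 && momentum < 1)) abort("momentum must be in [0, 1)")
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (epochs < 0) abort("epochs must be >= 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 l2 = l2, seed = as.integer(seed),
                 validation_split = validation_split,
                 verbose = isTRUE(verbose)),
            class = "training_config")
}

# Generic minibatch training loop.
#   x: H x W x C x N array;  y: target (array for mse, vector for bce,
#   one-hot matrix for cce);  autoencoder mode when loss == "mse" and the
#   target is the input itself.
train_network <- function(layers, x, y, loss, cfg, sample_dim = 4L) {
  n <- dim(x)[sample_dim]
  history <- list()
  if (cfg$epochs == 0)
    return(list(layers = layers,
                history = tibble(epoch = integer(), loss = numeric(),
                                 accuracy = numeric(), val_loss = numeric(),
                                 val_accuracy = numeric())))
  state <- new_sgd_state(layers)

  take <- function(obj, idx) {
    if (is.null(dim(obj))) obj[idx]
    else if (length(dim(obj)) == 4) obj[, , , idx, drop = FALSE]
    else obj[idx, , drop = FALSE]
  }

  val_idx <- integer(0)
  train_idx <- seq_len(n)
  if (cfg$validation_split > 0 && n >= 5) {
    n_val <- max(1L, floor(cfg$validation_split * n))
    val_idx <- with_seed(derive_seed(cfg$seed, 999L), sample(n, n_val))
    train_idx <- setdiff(train_idx, val_idx)
  }
  xv <- if (length(val_idx)) take(x, val_idx)
  yv <- if (length(val_idx)) take(y, val_idx)

  acc_of <- function(out, target) {
    if (loss == "bce") mean((out > 0.5) == (target > 0.5))
    else if (loss == "cce")
      mean(max.col(out, ties.method = "first") ==
           max.col(target, ties.method = "first"))
    else NA_real_
  }

  with_seed(derive_seed(cfg$seed, 1L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      ep_acc <- 0
      ep_n <- 0
      for (bi in batches) {
        xb <- take(x, bi)
        yb <- take(y, bi)
        fw <- nn_forward(layers, xb, training = TRUE)
        out <- fw$out
        lv <- loss_value(loss, out, yb)
        if (!is.finite(lv))
          abort(paste0("training diverged (non-finite loss) at epoch ", ep))
        nb <- length(bi)
        if (loss == "mse") {
          grad <- 2 * (out - yb) / length(out)
          grads <- nn_backward(layers, fw$caches, grad)
        } else if (loss == "bce") {
          delta <- (out - matrix(yb, ncol = 1)) / nb
          grads <- nn_backward(layers, fw$caches, delta, last_delta_pre = TRUE)
        } else {
          delta <- (out - yb) / nb
          grads <- nn_backward(layers, fw$caches, delta, last_delta_pre = TRUE)
        }
        layers <- bn_update_running(layers, fw$caches)
        up <- sgd_step(layers, state, grads, cfg$learning_rate, cfg$momentum,
                       cfg$l2)
        layers <- up$layers
        state <- up$state
        ep_loss <- ep_loss + lv * nb
        a <- acc_of(out, yb)
        if (!is.na(a)) ep_acc <- ep_acc + a * nb
        ep_n <- ep_n + nb
      }
      vl <- NA_real_
      va <- NA_real_
      if (length(val_idx)) {
        vout <- nn_forward(layers, xv, training = FALSE)$out
        vl <- loss_value(loss, vout, yv)
        va <- acc_of(vout, yv)
      }
      history[[ep]] <- tibble(epoch = ep, loss = ep_loss / ep_n,
                              accuracy = if (loss == "mse") NA_real_
                                         else ep_acc / ep_n,
                              val_loss = vl, val_accuracy = va)
      if (cfg$verbose)
        message(sprintf("epoch %d/%d  loss %.6f", ep, cfg$epochs,
                        ep_loss / ep_n))
    }
  })
  layers <- calibrate_bn(layers, if (length(val_idx)) take(x, train_idx)
                                 else x, cfg$batch_size)
  list(layers = layers, history = dplyr::bind_rows(history))
}

# Re-estimate batch-norm running moments with the final weights.
# During SGD the running averages trail the (fast-moving) parameters, so
# inference-mode normalization can be badly mis-scaled after short
# training runs. This pass walks the layers in order, computing each BN
# layer's input moments over the whole calibration set with all earlier
# layers already in inference mode, and freezes those moments as the
# running statistics. Dropout stays off: the moments must describe the
# activations exactly as inference will see them.
calibrate_bn <- function(layers, x, batch_size = 32L) {
  if (!any(vapply(layers, function(l) l$type == "bn", logical(1))))
    return(layers)
  n <- dim(x)[4]
  chunks <- lapply(split(seq_len(n), ceiling(seq_len(n) / batch_size)),
                   function(s) x[, , , s, drop = FALSE])
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "bn") {
      tot <- 0
      s1 <- 0
      s2 <- 0
      for (ch in chunks) {
        m <- channel_matrix(ch)
        s1 <- s1 + colSums(m)
        s2 <- s2 + colSums(m^2)
        tot <- tot + nrow(m)
      }
      layers[[i]]$rmean <- s1 / tot
      layers[[i]]$rvar <- pmax(s2 / tot - (s1 / tot)^2, 0)
      l <- layers[[i]]
    }
    if (!(l$type %in% c("dropout")))
      chunks <- lapply(chunks, function(ch)
        nn_forward(list(l), ch, training = FALSE)$out)
  }
  layers
}

# chunked inference-mode forward pass
nn_predict <- function(layers, x, batch_size = 32L) {
  n <- dim(x)[4]
  outs <- list()
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    outs[[length(outs) + 1]] <-
      nn_forward(layers, x[, , , s, drop = FALSE], training = FALSE)$out
  }
  if (is.matrix(outs[[1]])) do.call(rbind, outs)
  else {
    d <- dim(outs[[1]])
    out <- array(0, c(d[1:3], n))
    at <- 0
    for (o in outs) {
      k <- dim(o)[4]
      out[, , , at + seq_len(k)] <- o
      at <- at + k
    }
    out
  }
}
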