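# Independent brute-force reference implementations used to check the
# compiled kernels and the metric functions. Deliberately naive: direct
# summation, exhaustive pair counting, no shared code with the package.

oracle_conv2d <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  k <- dim(w)[1]; F <- dim(w)[4]
  p <- k %/% 2
  out <- array(0, c(H, W, F))
  for (f in seq_len(F)) for (h in seq_len(H)) for (wd in seq_len(W)) {
    s <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) for (c in seq_len(C)) {
      hh <- h + i - 1 - p
      ww <- wd + j - 1 - p
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
        s <- s + w[i, j, c, f] * x[hh, ww, c]
    }
    out[h, wd, f] <- s + b[f]
  }
  out
}

oracle_maxpool <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  Ho <- H %/% 2; Wo <- W %/% 2
  out <- array(0, c(Ho, Wo, C))
  for (c in seq_len(C)) for (i in seq_len(Ho)) for (j in seq_len(Wo))
    out[i, j, c] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  out
}

# Mann-Whitney AUC by exhaustive pair comparison, ties counted 1/2
oracle_auc <- function(truth, scores) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# confusion counts by direct pair enumeration
oracle_confusion <- function(truth, predicted, classes) {
  k <- length(classes)
  cm <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    cm[i, j] <- sum(truth == classes[i] & predicted == classes[j])
  cm
}

# coordinate-mapping oracle for an exact 90-degree CCW rotation of a
# square image: output[i, j] = input[j, n + 1 - i]
oracle_rot90 <- function(x) {
  n <- dim(x)[1]
  out <- array(0, dim(x))
  for (i in seq_len(n)) for (j in seq_len(n)) for (c in seq_len(dim(x)[3]))
    out[i, j, c] <- x[j, n + 1 - i, c]
  out
}

random_image <- function(n = 8, seed = NULL, label = "myeloblast") {
  if (!is.null(seed)) set.seed(seed)
  image_sample(array(runif(n * n * 3), c(n, n, 3)), label = label)
}
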