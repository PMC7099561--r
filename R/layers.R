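# Layer primitives of the segmentation network. Feature maps are npix x C
# matrices (npix = h*w, column-major pixel order); every forward function
# returns list(out, cache, params) where `cache` is NULL outside training
# and `params` carries updated batch-norm running statistics. Hot paths
# (im2col, batch norm, ReLU, pooling, upsampling) live in src/ops.cpp; the
# convolution GEMMs go through BLAS.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

rowrep <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

he_uniform <- function(n_in, n_out, fan_in) {
  l <- sqrt(6 / fan_in)
  matrix(runif(n_in * n_out, -l, l), n_in, n_out)
}

init_conv <- function(cin, cout, k) {
  list(W = he_uniform(k * k * cin, cout, k * k * cin), b = numeric(cout))
}

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c))
}

init_conv_block <- function(cin, cout, k) {
  list(c1 = init_conv(cin, cout, k), bn1 = init_bn(cout),
       c2 = init_conv(cout, cout, k), bn2 = init_bn(cout))
}

init_se <- function(c, reduction) {
  hid <- max(1L, c %/% reduction)
  list(W1 = he_uniform(c, hid, c), b1 = numeric(hid),
       W2 = he_uniform(hid, c, hid), b2 = numeric(c))
}

conv_fwd <- function(x, p, h, w, k, training) {
  patches <- cpp_im2col(x, h, w, k)
  out <- cpp_addbias(patches %*% p$W, p$b)
  list(out = out,
       cache = if (training) list(patches = patches, h = h, w = w, k = k,
                                  cin = ncol(x)))
}

conv_bwd <- function(dout, cache, p) {
  dW <- crossprod(cache$patches, dout)
  db <- colSums(dout)
  dx <- cpp_col2im(dout %*% t(p$W), cache$h, cache$w, cache$k, cache$cin)
  list(dx = dx, grads = list(W = dW, b = db))
}

bn_fwd <- function(x, p, training, batch_stats = training) {
  if (training || batch_stats) {
    r <- cpp_bn_fwd_train(x, p$gamma, p$beta, BN_EPS)
    if (training) {
      p$rmean <- (1 - BN_MOMENTUM) * p$rmean + BN_MOMENTUM * r$mean
      p$rvar <- (1 - BN_MOMENTUM) * p$rvar + BN_MOMENTUM * r$var
    }
    list(out = r$out,
         cache = if (training) list(xhat = r$xhat, invstd = r$invstd),
         params = p)
  } else {
    list(out = cpp_bn_fwd_eval(x, p$gamma, p$beta, p$rmean, p$rvar, BN_EPS),
         cache = NULL, params = p)
  }
}

bn_bwd <- function(dout, cache, p) {
  r <- cpp_bn_bwd(dout, cache$xhat, cache$invstd, p$gamma)
  list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

conv_block_fwd <- function(x, p, h, w, k, training, batch_stats = training) {
  s1 <- conv_fwd(x, p$c1, h, w, k, training)
  n1 <- bn_fwd(s1$out, p$bn1, training, batch_stats); p$bn1 <- n1$params
  a1 <- cpp_relu(n1$out)
  s2 <- conv_fwd(a1, p$c2, h, w, k, training)
  n2 <- bn_fwd(s2$out, p$bn2, training, batch_stats); p$bn2 <- n2$params
  a2 <- cpp_relu(n2$out)
  cache <- if (training) {
    list(c1 = s1$cache, bn1 = n1$cache, r1 = a1,
         c2 = s2$cache, bn2 = n2$cache, r2 = a2)
  }
  list(out = a2, cache = cache, params = p)
}

conv_block_bwd <- function(dout, cache, p) {
  d <- cpp_relu_bwd(dout + 0, cache$r2)  # +0 forces a private copy
  b2 <- bn_bwd(d, cache$bn2, p$bn2)
  s2 <- conv_bwd(b2$dx, cache$c2, p$c2)
  d <- cpp_relu_bwd(s2$dx, cache$r1)
  b1 <- bn_bwd(d, cache$bn1, p$bn1)
  s1 <- conv_bwd(b1$dx, cache$c1, p$c1)
  list(dx = s1$dx,
       grads = list(c1 = s1$grads, bn1 = b1$grads,
                    c2 = s2$grads, bn2 = b2$grads))
}

# Squeeze-and-excitation: global average pool -> dense/ReLU -> dense/sigmoid
# -> per-channel multiplicative weight in (0, 1).
se_fwd <- function(x, p, training) {
  z <- colMeans(x)
  a1 <- as.numeric(z %*% p$W1) + p$b1
  h1 <- pmax(a1, 0)
  a2 <- as.numeric(h1 %*% p$W2) + p$b2
  s <- sigmoid(a2)
  out <- cpp_colscale(x, s)
  cache <- if (training) list(x = x, z = z, h1 = h1, a1 = a1, s = s)
  list(out = out, cache = cache, scale = s)
}

se_bwd <- function(dout, cache, p) {
  n <- nrow(dout)
  s <- cache$s
  ds <- colSums(dout * cache$x)
  dx <- cpp_colscale(dout, s)
  da2 <- ds * s * (1 - s)
  dW2 <- outer(cache$h1, da2)
  db2 <- da2
  dh1 <- as.numeric(p$W2 %*% da2) * (cache$a1 > 0)
  dW1 <- outer(cache$z, dh1)
  db1 <- dh1
  dz <- as.numeric(p$W1 %*% dh1)
  dx <- cpp_addbias(dx, dz / n)
  list(dx = dx,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# Pixelwise binary cross-entropy on logits (numerically stable).
bce_with_logits <- function(z, y) {
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  dz <- (sigmoid(z) - y) / length(z)
  list(loss = loss, dz = dz)
}

# Soft Dice loss on logits.
dice_with_logits <- function(z, y, smooth = 1) {
  p <- sigmoid(z)
  num <- 2 * sum(p * y) + smooth
  den <- sum(p) + sum(y) + smooth
  loss <- 1 - num / den
  dp <- -(2 * y * den - num) / den^2
  list(loss = loss, dz = dp * p * (1 - p))
}
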