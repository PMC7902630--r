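# Differentiable layer primitives over (H, W, C, N) arrays. Convolution,
# pooling and transposed convolution run in compiled code; batch norm, ReLU,
# sigmoid, dropout and squeeze-excitation are vectorised R. Each *_fw returns
# the output plus whatever the matching *_bw needs.

sigmoid <- function(z) 1 / (1 + exp(-z))

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

bn_fw <- function(x, gamma, beta, rmean, rvar, training, momentum, eps) {
  if (training) {
    st <- nn_channel_stats(x)
    mu <- st$mean; va <- st$var
    new_mean <- momentum * rmean + (1 - momentum) * mu
    new_var <- momentum * rvar + (1 - momentum) * va
  } else {
    mu <- rmean; va <- rvar
    new_mean <- rmean; new_var <- rvar
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- nn_scale_shift(x, ivar, -mu * ivar)
  y <- nn_scale_shift(xhat, gamma, beta)
  list(y = y, cache = list(xhat = xhat, ivar = ivar, gamma = gamma),
       mean = new_mean, var = new_var)
}

bn_bw <- function(dy, cache) nn_bn_bw(dy, cache$xhat, cache$gamma, cache$ivar)

# ReLU derivative is recovered from the output (y > 0 iff input > 0).
relu_fw <- function(x) pmax(x, 0)
relu_bw <- function(dy, y) dy * (y > 0)

dropout_fw <- function(x, rate) {
  # inverted dropout; mask drawn from the session RNG (seeded by the caller)
  mask <- array(stats::rbinom(length(x), 1L, 1 - rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

# Squeeze-and-excitation: global average pool -> bottleneck MLP -> sigmoid gate.
se_fw <- function(x, w1, b1, w2, b2) {
  d <- dim(x)
  hw <- d[1] * d[2]
  z <- t(matrix(colSums(matrix(x, hw, d[3] * d[4])), d[3], d[4])) / hw  # (N, C)
  h_pre <- sweep(z %*% w1, 2, b1, "+")
  h <- pmax(h_pre, 0)
  a <- sigmoid(sweep(h %*% w2, 2, b2, "+"))                            # (N, C)
  scale <- array(rep(t(a), each = hw), d)
  list(y = x * scale,
       cache = list(x = x, z = z, h_pre = h_pre, h = h, a = a, scale = scale,
                    w1 = w1, w2 = w2))
}

se_bw <- function(dy, cache) {
  d <- dim(cache$x)
  hw <- d[1] * d[2]
  # through the product y = x * scale
  dx1 <- dy * cache$scale
  da <- t(matrix(colSums(matrix(dy * cache$x, hw, d[3] * d[4])), d[3], d[4]))
  dpre2 <- da * cache$a * (1 - cache$a)                 # (N, C)
  dw2 <- t(cache$h) %*% dpre2
  db2 <- colSums(dpre2)
  dh <- (dpre2 %*% t(cache$w2)) * (cache$h_pre > 0)
  dw1 <- t(cache$z) %*% dh
  db1 <- colSums(dh)
  dz <- dh %*% t(cache$w1)                              # (N, C)
  dx2 <- array(rep(t(dz), each = hw), d) / hw
  list(dx = dx1 + dx2, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(x, c1) {
  d <- dim(x)
  list(a = x[, , seq_len(c1), , drop = FALSE],
       b = x[, , (c1 + 1):d[3], , drop = FALSE])
}
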