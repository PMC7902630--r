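# Double-precision reference implementation of the plain U-Net forward pass,
# written independently with naive loops/shifts. Used to validate the float32
# compiled path and its gradients on tiny inputs.

ref_conv2d <- function(x, w, b) {
  d <- dim(x); k <- dim(w)[1]; p <- (k - 1) / 2; nf <- dim(w)[4]
  y <- array(0, c(d[1], d[2], nf, d[4]))
  for (n in 1:d[4]) for (f in 1:nf) {
    acc <- matrix(b[f], d[1], d[2])
    for (cc in 1:d[3]) for (a in 1:k) for (bb in 1:k) {
      xs <- matrix(0, d[1], d[2])
      hsrc <- (1:d[1]) + a - 1 - p; wsrc <- (1:d[2]) + bb - 1 - p
      hv <- which(hsrc >= 1 & hsrc <= d[1]); wv <- which(wsrc >= 1 & wsrc <= d[2])
      xs[hv, wv] <- x[hsrc[hv], wsrc[wv], cc, n]
      acc <- acc + xs * w[a, bb, cc, f]
    }
    y[, , f, n] <- acc
  }
  y
}

ref_bn <- function(x, gamma, beta, eps) {
  d <- dim(x); y <- x
  for (cc in 1:d[3]) {
    v <- x[, , cc, , drop = FALSE]
    mu <- mean(v); va <- mean((v - mu)^2)
    y[, , cc, ] <- (v - mu) / sqrt(va + eps) * gamma[cc] + beta[cc]
  }
  y
}

ref_pool <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1] / 2, d[2] / 2, d[3], d[4]))
  for (n in 1:d[4]) for (cc in 1:d[3])
    for (i in 1:(d[1] / 2)) for (j in 1:(d[2] / 2))
      y[i, j, cc, n] <- max(x[2 * i - 1:0, 2 * j - 1:0, cc, n])
  y
}

ref_upconv <- function(x, w, b) {
  d <- dim(x); nf <- dim(w)[4]
  y <- array(0, c(2 * d[1], 2 * d[2], nf, d[4]))
  for (n in 1:d[4]) for (f in 1:nf) {
    acc <- matrix(b[f], 2 * d[1], 2 * d[2])
    for (cc in 1:d[3]) for (a in 1:2) for (bb in 1:2)
      acc[seq(a, 2 * d[1], 2), seq(bb, 2 * d[2], 2)] <-
        acc[seq(a, 2 * d[1], 2), seq(bb, 2 * d[2], 2)] + x[, , cc, n] * w[a, bb, cc, f]
    y[, , f, n] <- acc
  }
  y
}

ref_block <- function(prefix, x, P, eps) {
  p <- function(nm) P[[paste0(prefix, ".", nm)]]
  h <- pmax(ref_bn(ref_conv2d(x, p("conv1.w"), p("conv1.b")),
                   p("bn1.gamma"), p("bn1.beta"), eps), 0)
  pmax(ref_bn(ref_conv2d(h, p("conv2.w"), p("conv2.b")),
              p("bn2.gamma"), p("bn2.beta"), eps), 0)
}

ref_unet_loss <- function(m, x, y) {
  P <- m$params; cfg <- m$cfg; eps <- cfg$bn_eps
  skips <- list(); h <- x
  for (l in 1:cfg$depth) {
    a <- ref_block(paste0("enc", l), h, P, eps)
    skips[[l]] <- a
    h <- ref_pool(a)
  }
  h <- ref_block("bott", h, P, eps)
  for (l in rev(1:cfg$depth)) {
    up <- ref_upconv(h, P[[paste0("dec", l, ".up.w")]],
                     P[[paste0("dec", l, ".up.b")]])
    cc <- array(0, c(dim(up)[1], dim(up)[2],
                     dim(up)[3] + dim(skips[[l]])[3], dim(up)[4]))
    cc[, , 1:dim(up)[3], ] <- up
    cc[, , (dim(up)[3] + 1):dim(cc)[3], ] <- skips[[l]]
    h <- ref_block(paste0("dec", l), cc, P, eps)
  }
  logits <- ref_conv2d(h, P$head.w, P$head.b)
  mean(pmax(-logits, 0) + log1p(exp(-abs(logits))) + (1 - y) * logits)
}

# independent layer-by-layer trainable parameter enumeration from a config
ref_param_count <- function(cfg) {
  conv_p <- function(k, cin, cout) k * k * cin * cout + cout
  bn_p <- function(c) 2 * c
  block_p <- function(cin, cout) {
    n <- conv_p(3, cin, cout) + bn_p(cout) + conv_p(3, cout, cout) + bn_p(cout)
    if (cfg$arch == "resunet") n <- n + conv_p(1, cin, cout)
    if (cfg$arch == "seunet") {
      cr <- max(1, cout %/% cfg$se_ratio)
      n <- n + cout * cr + cr + cr * cout + cout
    }
    n
  }
  total <- 0
  cin <- cfg$in_channels
  for (l in 1:cfg$depth) {
    f <- cfg$base_filters * 2^(l - 1)
    total <- total + block_p(cin, f)
    cin <- f
  }
  fb <- cfg$base_filters * 2^cfg$depth
  total <- total + block_p(cin, fb)
  cup <- fb
  for (l in rev(1:cfg$depth)) {
    f <- cfg$base_filters * 2^(l - 1)
    total <- total + (2 * 2 * cup * f + f)  # transposed conv
    total <- total + block_p(2 * f, f)
    cup <- f
  }
  total + conv_p(1, cfg$base_filters, 1)
}
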