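#' Configuration of a 2D encoder-decoder segmentation network
#'
#' The network takes `input_size` slices with `in_channels` channels and
#' returns a per-pixel foreground probability map of the same size. In the
#' auto-context cascade, stage s uses `in_channels = s`: the raw image slice
#' plus the binary masks of the previous stages as extra channels.
#'
#' @param arch `"unet"` (plain double-conv blocks), `"resunet"` (residual
#'   blocks: a 3x3 conv path summed with a 1x1 projection), or `"seunet"`
#'   (double-conv blocks followed by squeeze-and-excitation recalibration).
#' @param in_channels number of input channels, 1, 2 or 3.
#' @param depth number of 2x down-sampling steps.
#' @param base_filters filters at the first level; doubled at each level.
#' @param dropout_rate dropout rate in the bottleneck (default 0.2).
#' @param se_ratio squeeze-and-excitation reduction ratio, used by `"seunet"`
#'   only; the same ratio is applied at every level.
#' @param input_size spatial slice size `(H, W)`; must be divisible by
#'   `2^depth`.
#' @param bn_momentum,bn_eps batch-normalisation running-statistics momentum
#'   and variance floor.
#' @return An object of class `seg_model_config`.
#' @export
seg_model_config <- function(arch = c("unet", "resunet", "seunet"),
                             in_channels = 1L, depth = 4L, base_filters = 16L,
                             dropout_rate = 0.2, se_ratio = 8L,
                             input_size = c(256L, 256L),
                             bn_momentum = 0.9, bn_eps = 1e-3) {
  arch <- match.arg(arch)
  in_channels <- as.integer(in_channels)
  if (!in_channels %in% 1:3)
    stop("seg_model_config: in_channels must be 1, 2 or 3")
  depth <- as.integer(depth); base_filters <- as.integer(base_filters)
  if (depth < 1L || base_filters < 1L)
    stop("seg_model_config: depth and base_filters must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("seg_model_config: dropout_rate must be in [0, 1)")
  input_size <- as.integer(rep(input_size, length.out = 2))
  if (any(input_size %% 2L^depth != 0L))
    stop("seg_model_config: input_size ", paste(input_size, collapse = "x"),
         " is not divisible by 2^depth = ", 2L^depth)
  structure(list(arch = arch, in_channels = in_channels, depth = depth,
                 base_filters = base_filters, dropout_rate = dropout_rate,
                 se_ratio = as.integer(se_ratio), input_size = input_size,
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "seg_model_config")
}

# filters at encoder level l (1-based); bottleneck is level depth+1
level_filters <- function(cfg, l) cfg$base_filters * 2L^(l - 1L)

he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

block_param_init <- function(cfg, cin, cout) {
  p <- list(
    conv1.w = he_init(c(3, 3, cin, cout), 9 * cin), conv1.b = numeric(cout),
    bn1.gamma = rep(1, cout), bn1.beta = numeric(cout),
    conv2.w = he_init(c(3, 3, cout, cout), 9 * cout), conv2.b = numeric(cout),
    bn2.gamma = rep(1, cout), bn2.beta = numeric(cout))
  if (cfg$arch == "resunet") {
    p$proj.w <- he_init(c(1, 1, cin, cout), cin)
    p$proj.b <- numeric(cout)
  }
  if (cfg$arch == "seunet") {
    cr <- max(1L, cout %/% cfg$se_ratio)
    p$se.w1 <- he_init(c(cout, cr), cout)
    p$se.b1 <- numeric(cr)
    p$se.w2 <- he_init(c(cr, cout), cr)
    p$se.b2 <- numeric(cout)
  }
  p
}

block_state_init <- function(cout) {
  list(bn1.mean = numeric(cout), bn1.var = rep(1, cout),
       bn2.mean = numeric(cout), bn2.var = rep(1, cout))
}

prefix_names <- function(prefix, lst) setNames(lst, paste0(prefix, ".", names(lst)))

#' Build a 2D segmentation network with deterministic seeded initialisation
#'
#' The contracting path applies `depth` repetitions of a conv block (two
#' 3x3 conv + batch norm + ReLU layers, with the architecture's variation)
#' followed by 2x2 max pooling, doubling the filter count at each level. The
#' bottleneck block carries dropout. The expanding path mirrors the encoder
#' with stride-2 transposed convolutions and skip concatenation. A 1x1
#' convolution with sigmoid yields per-pixel probabilities.
#'
#' @param cfg a [seg_model_config()].
#' @param seed integer; the same seed always gives identical initial weights.
#' @return An object of class `seg_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "seg_model_config"))
  with_seed(seed, {
    params <- list(); state <- list()
    cin <- cfg$in_channels
    for (l in seq_len(cfg$depth)) {
      f <- level_filters(cfg, l)
      params <- c(params, prefix_names(paste0("enc", l), block_param_init(cfg, cin, f)))
      state <- c(state, prefix_names(paste0("enc", l), block_state_init(f)))
      cin <- f
    }
    fb <- level_filters(cfg, cfg$depth + 1L)
    params <- c(params, prefix_names("bott", block_param_init(cfg, cin, fb)))
    state <- c(state, prefix_names("bott", block_state_init(fb)))
    cup <- fb
    for (l in rev(seq_len(cfg$depth))) {
      f <- level_filters(cfg, l)
      up <- list(up.w = he_init(c(2, 2, cup, f), 4 * cup), up.b = numeric(f))
      params <- c(params, prefix_names(paste0("dec", l), up))
      params <- c(params, prefix_names(paste0("dec", l), block_param_init(cfg, 2L * f, f)))
      state <- c(state, prefix_names(paste0("dec", l), block_state_init(f)))
      cup <- f
    }
    params$head.w <- he_init(c(1, 1, cfg$base_filters, 1), cfg$base_filters)
    # background-prior initialisation: the head starts predicting background
    # everywhere, which stabilises early training on heavily imbalanced masks
    params$head.b <- -2
    structure(list(cfg = cfg, params = params, state = state),
              class = "seg_model")
  })
}

#' @export
print.seg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<seg_model> %s, %d input channel(s), depth %d, base %d, %d parameters\n",
              x$cfg$arch, x$cfg$in_channels, x$cfg$depth, x$cfg$base_filters, np))
  invisible(x)
}

#' Count of trainable parameters of a model
#' @param m a `seg_model`.
#' @return integer count (convolution and BN scale/shift weights; running
#'   statistics are not trainable).
#' @export
n_parameters <- function(m) sum(vapply(m$params, length, 0L))

# ---- forward / backward -----------------------------------------------------

next_slot <- function(slots) {
  slots$i <- slots$i + 1L
  slots$i - 1L
}

block_fw <- function(prefix, x, P, S, cfg, training, state_out, slots) {
  p <- function(n) P[[paste0(prefix, ".", n)]]
  s <- function(n) S[[paste0(prefix, ".", n)]]
  s1 <- next_slot(slots); s2 <- next_slot(slots)
  c1y <- nn_conv2d_fw_pool(x, p("conv1.w"), p("conv1.b"), s1)
  b1 <- bn_fw(c1y, p("bn1.gamma"), p("bn1.beta"), s("bn1.mean"), s("bn1.var"),
              training, cfg$bn_momentum, cfg$bn_eps)
  r1y <- relu_fw(b1$y)
  c2y <- nn_conv2d_fw_pool(r1y, p("conv2.w"), p("conv2.b"), s2)
  b2 <- bn_fw(c2y, p("bn2.gamma"), p("bn2.beta"), s("bn2.mean"), s("bn2.var"),
              training, cfg$bn_momentum, cfg$bn_eps)
  state_out[[paste0(prefix, ".bn1.mean")]] <- b1$mean
  state_out[[paste0(prefix, ".bn1.var")]] <- b1$var
  state_out[[paste0(prefix, ".bn2.mean")]] <- b2$mean
  state_out[[paste0(prefix, ".bn2.var")]] <- b2$var
  cache <- list(xdim = dim(x), r1dim = dim(r1y), c1slot = s1, c2slot = s2,
                bn1 = b1$cache, bn2 = b2$cache, r1y = r1y)
  if (cfg$arch == "resunet") {
    sp <- next_slot(slots)
    pry <- nn_conv2d_fw_pool(x, p("proj.w"), p("proj.b"), sp)
    cache$projslot <- sp
    r2y <- relu_fw(b2$y + pry)
    cache$r2y <- r2y
    list(y = r2y, cache = cache)
  } else {
    r2y <- relu_fw(b2$y)
    cache$r2y <- r2y
    if (cfg$arch == "seunet") {
      se <- se_fw(r2y, p("se.w1"), p("se.b1"), p("se.w2"), p("se.b2"))
      cache$se <- se$cache
      list(y = se$y, cache = cache)
    } else {
      list(y = r2y, cache = cache)
    }
  }
}

block_bw <- function(prefix, dy, cache, P, cfg, grads, need_input_grad = TRUE) {
  p <- function(n) P[[paste0(prefix, ".", n)]]
  g <- function(n, v) {
    key <- paste0(prefix, ".", n)
    grads[[key]] <- if (is.null(grads[[key]])) v else grads[[key]] + v
  }
  if (cfg$arch == "seunet") {
    seb <- se_bw(dy, cache$se)
    g("se.w1", seb$dw1); g("se.b1", seb$db1)
    g("se.w2", seb$dw2); g("se.b2", seb$db2)
    dy <- seb$dx
  }
  dpre <- relu_bw(dy, cache$r2y)
  dx_extra <- 0
  if (cfg$arch == "resunet") {
    prb <- nn_conv2d_bw_pool(cache$projslot, p("proj.w"), dpre, cache$xdim,
                             need_input_grad)
    g("proj.w", prb$dw); g("proj.b", prb$db)
    if (need_input_grad) dx_extra <- prb$dx
  }
  b2 <- bn_bw(dpre, cache$bn2)
  g("bn2.gamma", b2$dgamma); g("bn2.beta", b2$dbeta)
  c2 <- nn_conv2d_bw_pool(cache$c2slot, p("conv2.w"), b2$dx, cache$r1dim, TRUE)
  g("conv2.w", c2$dw); g("conv2.b", c2$db)
  dr1 <- relu_bw(c2$dx, cache$r1y)
  b1 <- bn_bw(dr1, cache$bn1)
  g("bn1.gamma", b1$dgamma); g("bn1.beta", b1$dbeta)
  c1 <- nn_conv2d_bw_pool(cache$c1slot, p("conv1.w"), b1$dx, cache$xdim,
                          need_input_grad)
  g("conv1.w", c1$dw); g("conv1.b", c1$db)
  if (need_input_grad) c1$dx + dx_extra else NULL
}

# Full forward pass. Returns logits, probabilities, per-layer caches and the
# updated BN running statistics. Dropout uses the session RNG.
model_forward <- function(m, x, training = FALSE) {
  cfg <- m$cfg; P <- m$params; S <- m$state
  state_out <- new.env(parent = emptyenv())
  slots <- new.env(parent = emptyenv()); slots$i <- 0L
  caches <- list(); skips <- list(); pools <- list()
  h <- x
  for (l in seq_len(cfg$depth)) {
    r <- block_fw(paste0("enc", l), h, P, S, cfg, training, state_out, slots)
    caches[[paste0("enc", l)]] <- r$cache
    skips[[l]] <- r$y
    pl <- nn_maxpool2_fw(r$y)
    pools[[l]] <- list(idx = pl$idx, xdim = dim(r$y))
    h <- pl$y
  }
  r <- block_fw("bott", h, P, S, cfg, training, state_out, slots)
  caches$bott <- r$cache
  h <- r$y
  if (training && cfg$dropout_rate > 0) {
    dr <- dropout_fw(h, cfg$dropout_rate)
    caches$dropout <- dr$mask
    h <- dr$y
  }
  for (l in rev(seq_len(cfg$depth))) {
    us <- next_slot(slots)
    up <- nn_upconv2_fw(h, P[[paste0("dec", l, ".up.w")]],
                        P[[paste0("dec", l, ".up.b")]], us)
    caches[[paste0("dec", l, ".upslot")]] <- us
    caches[[paste0("dec", l, ".updim")]] <- dim(h)
    cc <- concat_channels(up, skips[[l]])
    r <- block_fw(paste0("dec", l), cc, P, S, cfg, training, state_out, slots)
    caches[[paste0("dec", l)]] <- r$cache
    h <- r$y
  }
  hs <- next_slot(slots)
  logits <- nn_conv2d_fw_pool(h, P$head.w, P$head.b, hs)
  caches$headslot <- hs
  caches$headdim <- dim(h)
  list(logits = logits, prob = sigmoid(logits), caches = caches,
       pools = pools, state = as.list(state_out))
}

model_backward <- function(m, fwd, dlogits) {
  cfg <- m$cfg; P <- m$params
  grads <- new.env(parent = emptyenv())
  hb <- nn_conv2d_bw_pool(fwd$caches$headslot, P$head.w, dlogits, fwd$caches$headdim)
  grads$head.w <- hb$dw; grads$head.b <- hb$db
  dh <- hb$dx
  for (l in seq_len(cfg$depth)) {
    dcc <- block_bw(paste0("dec", l), dh, fwd$caches[[paste0("dec", l)]], P, cfg, grads)
    f <- level_filters(cfg, l)
    sp <- split_channels(dcc, f)
    dskip <- sp$b
    ub <- nn_upconv2_bw(fwd$caches[[paste0("dec", l, ".upslot")]],
                        P[[paste0("dec", l, ".up.w")]], sp$a,
                        fwd$caches[[paste0("dec", l, ".updim")]])
    grads[[paste0("dec", l, ".up.w")]] <- ub$dw
    grads[[paste0("dec", l, ".up.b")]] <- ub$db
    dh <- ub$dx
    # stash the skip gradient for the encoder pass
    grads[[paste0(".skipgrad", l)]] <- dskip
  }
  if (!is.null(fwd$caches$dropout)) dh <- dh * fwd$caches$dropout
  dh <- block_bw("bott", dh, fwd$caches$bott, P, cfg, grads)
  for (l in rev(seq_len(cfg$depth))) {
    dpool <- nn_maxpool2_bw(dh, fwd$pools[[l]]$idx, fwd$pools[[l]]$xdim)
    dsum <- dpool + grads[[paste0(".skipgrad", l)]]
    rm(list = paste0(".skipgrad", l), envir = grads)
    dh <- block_bw(paste0("enc", l), dsum, fwd$caches[[paste0("enc", l)]], P,
                   cfg, grads, need_input_grad = l > 1L)
  }
  as.list(grads)
}

# ---- inference --------------------------------------------------------------

#' Predict per-slice foreground probabilities for a slice stack
#'
#' Runs the model in inference mode: dropout disabled, batch normalisation
#' using running statistics. Deterministic given the weights.
#'
#' @param m a `seg_model` (or a stub created with [stub_seg_model()]).
#' @param s a [slice_stack()] whose channel count equals `m$cfg$in_channels`
#'   and whose spatial shape equals `m$cfg$input_size`.
#' @param ... unused.
#' @return A single-channel probability [slice_stack()] along the same axis.
#' @export
predict_stack <- function(m, s, ...) UseMethod("predict_stack")

#' @export
predict_stack.seg_model <- function(m, s, batch = 32L, ...) {
  stopifnot(inherits(s, "slice_stack"))
  d <- dim(s$slices)
  if (d[3] != m$cfg$in_channels)
    stop("predict_stack: stack has ", d[3], " channels but the model expects ",
         m$cfg$in_channels)
  if (!all(d[1:2] == m$cfg$input_size))
    stop("predict_stack: slices are ", d[1], "x", d[2],
         " but the model expects ", paste(m$cfg$input_size, collapse = "x"))
  out <- array(0, c(d[1], d[2], 1L, d[4]))
  for (start in seq(1L, d[4], by = batch)) {
    idx <- start:min(start + batch - 1L, d[4])
    x <- s$slices[, , , idx, drop = FALSE]
    out[, , 1L, idx] <- model_forward(m, x, training = FALSE)$prob
  }
  slice_stack(out, s$axis)
}

#' Oracle stand-in for a trained stage model
#'
#' Wraps a probability [volume()]; `predict_stack` simply slices it along the
#' requested axis. Used to test the cascade plumbing independently of
#' training.
#'
#' @param prob_volume a [volume()] of values in `[0, 1]`.
#' @param in_channels declared input channel count (contract checking only).
#' @return An object of class `c("stub_seg_model", "seg_model")`.
#' @export
stub_seg_model <- function(prob_volume, in_channels = 1L) {
  stopifnot(inherits(prob_volume, "volume"))
  structure(list(cfg = list(in_channels = as.integer(in_channels)),
                 prob_volume = prob_volume),
            class = c("stub_seg_model", "seg_model"))
}

#' @export
predict_stack.stub_seg_model <- function(m, s, ...) {
  d <- dim(s$slices)
  if (d[3] != m$cfg$in_channels)
    stop("predict_stack: stack has ", d[3], " channels but the stub expects ",
         m$cfg$in_channels)
  extract_slices(m$prob_volume, s$axis)
}

# ---- checkpoint serialisation ----------------------------------------------

#' Save / load a segmentation model checkpoint
#'
#' Weights and BN running statistics go into an RDS file; the architecture
#' configuration is stored alongside as YAML for exact rehydration.
#'
#' @param m a `seg_model`.
#' @param path basename for the checkpoint (writes `<path>.rds` and
#'   `<path>.yaml`).
#' @return `path`, invisibly.
#' @export
save_seg_model <- function(m, path) {
  saveRDS(list(params = m$params, state = m$state), paste0(path, ".rds"))
  yaml::write_yaml(unclass(m$cfg), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_seg_model
#' @export
load_seg_model <- function(path) {
  blob <- readRDS(paste0(path, ".rds"))
  cfgl <- yaml::read_yaml(paste0(path, ".yaml"))
  cfg <- do.call(seg_model_config, cfgl)
  structure(list(cfg = cfg, params = blob$params, state = blob$state),
            class = "seg_model")
}
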