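#' Training hyper-parameters
#'
#' Defaults follow the study conditions of the segmentation framework:
#' Adam at learning rate 1e-4, batch size 20, up to 200 epochs with
#' early stopping on the training loss, binary cross entropy cost.
#'
#' @param learning_rate Adam step size.
#' @param batch_size slices per mini-batch.
#' @param max_epochs maximum epochs per stage.
#' @param early_stop_patience epochs without a new best training loss before
#'   stopping.
#' @param seed seed for shuffling, dropout and weight initialisation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 20L,
                         max_epochs = 200L, early_stop_patience = 20L,
                         seed = 1L) {
  batch_size <- as.integer(batch_size); max_epochs <- as.integer(max_epochs)
  if (batch_size < 1L) stop("train_config: batch_size must be >= 1")
  if (max_epochs < 1L) stop("train_config: max_epochs must be >= 1")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Mean per-voxel binary cross entropy from logits (numerically stable):
# BCE = softplus(z) - y*z + softplus(-z)*0 ... expressed as softplus(-z) + (1-y)*z.
bce_from_logits <- function(logits, y) {
  mean(softplus(-logits) + (1 - y) * logits)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (opt$m[[k]] / bc1) / (sqrt(opt$v[[k]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train one stage network on a set of slices
#'
#' Runs shuffled mini-batch Adam on mean per-voxel binary cross entropy.
#' After every epoch the model with the lowest training loss so far is
#' checkpointed; training stops at `max_epochs` or when the training loss has
#' not improved for `early_stop_patience` epochs. The checkpointed (not the
#' final) weights are returned.
#'
#' @param model a `seg_model` from [build_model()].
#' @param x input slices, a `(H, W, C, N)` array.
#' @param y target masks, a `(H, W, 1, N)` array of 0/1.
#' @param cfg a [train_config()].
#' @param checkpoint_path optional basename; when given, the best model is
#'   also written there via [save_seg_model()].
#' @param verbose print per-epoch losses.
#' @return The trained `seg_model`, with the per-epoch loss history in
#'   attribute `"history"`.
#' @export
train_stage_model <- function(model, x, y, cfg, checkpoint_path = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(model, "seg_model"), inherits(cfg, "train_config"))
  dx <- dim(x)
  if (is.null(dx) || length(dx) != 4L) stop("train_stage_model: x must be (H,W,C,N)")
  if (dx[4] < 1L) stop("train_stage_model: empty training set")
  n <- dx[4]
  with_seed(cfg$seed, {
    opt <- adam_init(model$params)
    best_loss <- Inf; best <- NULL; stale <- 0L
    history <- numeric(0)
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      total <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- y[, , , idx, drop = FALSE]
        fwd <- model_forward(model, xb, training = TRUE)
        loss <- bce_from_logits(fwd$logits, yb)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        dlogits <- (fwd$prob - yb) / length(yb)
        grads <- model_backward(model, fwd, dlogits)
        st <- adam_step(model$params, grads, opt, cfg$learning_rate)
        model$params <- st$params; opt <- st$opt
        model$state <- fwd$state
        total <- total + loss * length(idx)
      }
      epoch_loss <- total / n
      history <- c(history, epoch_loss)
      if (verbose) message(sprintf("epoch %3d  bce %.5f", epoch, epoch_loss))
      if (epoch_loss < best_loss) {
        best_loss <- epoch_loss
        best <- list(params = model$params, state = model$state)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$early_stop_patience) break
      }
    }
    model$params <- best$params
    model$state <- best$state
    attr(model, "history") <- history
    attr(model, "best_loss") <- best_loss
    if (!is.null(checkpoint_path)) save_seg_model(model, checkpoint_path)
    model
  })
}

# Evaluate mean BCE of a model on slices without updating anything.
eval_bce <- function(model, x, y, batch = 32L) {
  n <- dim(x)[4]
  total <- 0
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fwd <- model_forward(model, x[, , , idx, drop = FALSE], training = FALSE)
    total <- total + bce_from_logits(fwd$logits, y[, , , idx, drop = FALSE]) * length(idx)
  }
  total / n
}
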