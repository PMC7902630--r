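#' Configuration of the three-stage auto-context cascade
#'
#' Stage s slices the volume along `axis_order[s]`, predicts each slice with a
#' 2D network whose input channels are the image plus the binary masks of all
#' previous stages, reassembles the 3D probability volume, binarises it and
#' keeps the largest 3D connected component. The third stage's mask is the
#' system output.
#'
#' @param axis_order permutation of the three anatomical axes; default
#'   coronal, sagittal, axial.
#' @param threshold probability binarisation threshold in (0,1); a voxel is
#'   foreground iff its probability is strictly greater.
#' @param connectivity 3D neighbourhood for connected components: 6, 18 or 26.
#' @param stage_configs list of three [seg_model_config()]s with
#'   `in_channels` 1, 2, 3 respectively.
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(axis_order = c("coronal", "sagittal", "axial"),
                           threshold = 0.5, connectivity = 26L,
                           stage_configs = NULL) {
  axis_order <- as.character(axis_order)
  if (length(axis_order) != 3L || !setequal(axis_order, ANATOMICAL_AXES))
    stop("cascade_config: axis_order must be a permutation of the three axes")
  if (threshold <= 0 || threshold >= 1)
    stop("cascade_config: threshold must be in (0, 1)")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("cascade_config: connectivity must be 6, 18 or 26")
  if (is.null(stage_configs))
    stage_configs <- lapply(1:3, function(s)
      seg_model_config("unet", in_channels = s))
  if (length(stage_configs) != 3L)
    stop("cascade_config: need exactly three stage configs")
  for (s in 1:3)
    if (stage_configs[[s]]$in_channels != s)
      stop("cascade_config: stage ", s, " must have in_channels = ", s)
  structure(list(axis_order = axis_order, threshold = threshold,
                 connectivity = as.integer(connectivity),
                 stage_configs = stage_configs),
            class = "cascade_config")
}

#' Binarise a probability volume
#'
#' A voxel becomes foreground iff its probability is strictly greater than
#' the threshold, so exact ties fall to background; idempotent on binary
#' input for any threshold in (0,1).
#'
#' @param p a [volume()] with values in `[0, 1]`.
#' @param threshold real in (0, 1).
#' @return A [label_volume()].
#' @export
binarize <- function(p, threshold = 0.5) {
  stopifnot(inherits(p, "volume"))
  if (any(p$data < 0 | p$data > 1))
    stop("binarize: input values must lie in [0, 1]")
  label_volume(array(as.double(p$data > threshold), dim(p$data)),
               p$spacing, p$axis_labels)
}

#' Keep only the largest 3D connected component of a mask
#'
#' Components are extracted under the given 3D connectivity; all foreground
#' voxels outside the largest component are zeroed. An empty mask is returned
#' unchanged (with a warning). Equal-size ties are broken in favour of the
#' component whose first voxel comes earliest in grid scan order.
#'
#' @param m a [label_volume()].
#' @param connectivity 6, 18 or 26.
#' @return A [label_volume()] with at most one component.
#' @export
largest_component <- function(m, connectivity = 26L) {
  stopifnot(inherits(m, "label_volume"))
  if (sum(m$data) == 0) {
    warning("largest_component: empty mask")
    return(m)
  }
  lab <- cc_label_3d(as.integer(m$data), dim(m$data), as.integer(connectivity))
  sizes <- tabulate(lab)
  keep <- which.max(sizes)  # first maximum = earliest first voxel in scan order
  label_volume(array(as.double(lab == keep), dim(m$data)),
               m$spacing, m$axis_labels)
}

#' Stack the image and prior-stage masks into a multi-channel slice stack
#'
#' Slice k carries channels `[image, prior1, prior2, ...]` in stage order.
#' Stage 1 passes no priors (a plain single-channel stack), stage 2 one, and
#' stage 3 two.
#'
#' @param image a [volume()] (normalised intensities).
#' @param priors list of 0-2 [label_volume()]s from earlier stages.
#' @param axis anatomical slicing axis.
#' @return A [slice_stack()] with `1 + length(priors)` channels.
#' @export
stack_stage_input <- function(image, priors = list(), axis) {
  stopifnot(inherits(image, "volume"))
  if (length(priors) > 2L)
    stop("stack_stage_input: at most two prior masks are supported")
  for (pr in priors) {
    if (!all(dim(pr$data) == dim(image$data)))
      stop("stack_stage_input: prior mask geometry does not match the image")
    if (!identical(pr$axis_labels, image$axis_labels))
      stop("stack_stage_input: prior mask axis labels do not match the image")
  }
  base <- extract_slices(image, axis)
  d <- dim(base$slices)
  out <- array(0, c(d[1], d[2], 1L + length(priors), d[4]))
  out[, , 1L, ] <- base$slices
  for (i in seq_along(priors))
    out[, , 1L + i, ] <- extract_slices(priors[[i]], axis)$slices
  slice_stack(out, axis)
}

#' Trained auto-context cascade
#'
#' @param stages list of three `seg_model`s (stage s has `in_channels = s`).
#' @param config a [cascade_config()].
#' @param normalizer the [fit_normalizer()] result fitted on the training
#'   volumes.
#' @return An object of class `cascade_model`.
#' @export
cascade_model <- function(stages, config, normalizer) {
  stopifnot(length(stages) == 3L, inherits(config, "cascade_config"))
  for (s in 1:3)
    if (stages[[s]]$cfg$in_channels != s)
      stop("cascade_model: stage ", s, " model must take ", s, " channels")
  structure(list(stages = stages, config = config, normalizer = normalizer),
            class = "cascade_model")
}

#' Run the full cascade on a raw (already resampled) volume
#'
#' Applies the stored normalizer, then for each stage: slice along the
#' stage's axis with the previous stages' masks as extra channels, predict,
#' reassemble, binarise, and reduce to the largest connected component. The
#' final stage's mask is returned; it has at most one component.
#'
#' @param cm a [cascade_model()].
#' @param raw a [volume()] matching the stage input size.
#' @param return_stages also return the intermediate stage masks.
#' @return A [label_volume()], or a list of three if `return_stages`.
#' @export
run_cascade <- function(cm, raw, return_stages = FALSE) {
  stopifnot(inherits(cm, "cascade_model"), inherits(raw, "volume"))
  img <- if (is.null(cm$normalizer)) raw else apply_normalizer(cm$normalizer, raw)
  masks <- list()
  for (s in 1:3) {
    axis <- cm$config$axis_order[s]
    stk <- stack_stage_input(img, masks, axis)
    probs <- tryCatch(predict_stack(cm$stages[[s]], stk),
                      error = function(e)
                        stop("cascade stage ", s, ": ", conditionMessage(e)))
    pvol <- assemble_volume(probs, raw)
    msk <- binarize(pvol, cm$config$threshold)
    msk <- withCallingHandlers(
      largest_component(msk, cm$config$connectivity),
      warning = function(w) {
        warning("cascade stage ", s, ": ", conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    masks[[s]] <- msk
  }
  if (return_stages) masks else masks[[3]]
}

#' Train the three cascade stages sequentially
#'
#' The normalizer is fitted on the training images only. Stage 1 trains on
#' image slices against the ground-truth masks; its post-processed
#' predictions on the training volumes (not the ground truth) become the
#' prior channel for stage 2 training, and likewise for stage 3 — matching
#' what the stages will see at inference time.
#'
#' @param train list of `phantom_sample`s or of `list(image =, label =)`
#'   pairs with uniform geometry.
#' @param cfg a [cascade_config()].
#' @param tcfg a [train_config()].
#' @param checkpoint_dir optional directory for per-stage checkpoints
#'   (`stage1`..`stage3`).
#' @param verbose print per-epoch losses.
#' @return A [cascade_model()].
#' @export
train_cascade <- function(train, cfg, tcfg, checkpoint_dir = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(cfg, "cascade_config"), inherits(tcfg, "train_config"))
  if (length(train) < 1L) stop("train_cascade: need at least one training pair")
  images <- lapply(train, `[[`, "image")
  labels <- lapply(train, `[[`, "label")
  norm <- fit_normalizer(images)
  imgs <- lapply(images, function(v) apply_normalizer(norm, v))
  nvol <- length(imgs)
  priors <- replicate(nvol, list(), simplify = FALSE)
  stages <- vector("list", 3L)
  stage_seeds <- derive_seeds(tcfg$seed, 3L)
  for (s in 1:3) {
    axis <- cfg$axis_order[s]
    xs <- lapply(seq_len(nvol), function(i)
      stack_stage_input(imgs[[i]], priors[[i]], axis)$slices)
    ys <- lapply(seq_len(nvol), function(i)
      extract_slices(labels[[i]], axis)$slices)
    x <- bind_slices(xs)
    y <- bind_slices(ys)
    model <- build_model(cfg$stage_configs[[s]], seed = stage_seeds[s])
    scfg <- tcfg; scfg$seed <- stage_seeds[s]
    ckpt <- if (is.null(checkpoint_dir)) NULL else {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      file.path(checkpoint_dir, paste0("stage", s))
    }
    model <- tryCatch(
      train_stage_model(model, x, y, scfg, checkpoint_path = ckpt,
                        verbose = verbose),
      error = function(e) stop("cascade stage ", s, ": ", conditionMessage(e)))
    stages[[s]] <- model
    if (s < 3L) {
      # post-processed predictions on the training volumes feed the next stage
      for (i in seq_len(nvol)) {
        stk <- stack_stage_input(imgs[[i]], priors[[i]], axis)
        pvol <- assemble_volume(predict_stack(model, stk), imgs[[i]])
        msk <- suppressWarnings(
          largest_component(binarize(pvol, cfg$threshold), cfg$connectivity))
        priors[[i]] <- c(priors[[i]], list(msk))
      }
    }
  }
  cascade_model(stages, cfg, norm)
}

# concatenate (H, W, C, N_i) arrays along the slice dimension
bind_slices <- function(lst) {
  d <- dim(lst[[1]])
  ns <- vapply(lst, function(a) dim(a)[4], 0L)
  out <- array(0, c(d[1], d[2], d[3], sum(ns)))
  at <- 0L
  for (a in lst) {
    out[, , , at + seq_len(dim(a)[4])] <- a
    at <- at + dim(a)[4]
  }
  out
}
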