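#' Random balanced specimen-level fold assignment
#'
#' Specimens (never individual slices) are shuffled and dealt round-robin
#' into k folds, so fold sizes differ by at most one. Deterministic given
#' the seed.
#'
#' @param ids vector of specimen identifiers.
#' @param k number of folds, `k <= length(ids)`.
#' @param seed integer seed.
#' @return An object of class `fold_assignment`: list with `k` and `mapping`
#'   (named integer vector, specimen id -> fold).
#' @export
make_folds <- function(ids, k, seed = 1L) {
  ids <- as.character(ids)
  n <- length(ids)
  k <- as.integer(k)
  if (k < 1L || k > n)
    stop("make_folds: k must be between 1 and the number of specimens (", n, ")")
  if (anyDuplicated(ids)) stop("make_folds: duplicated specimen ids")
  mapping <- with_seed(seed, {
    perm <- sample(ids)
    setNames(rep_len(seq_len(k), n), perm)[ids]
  })
  structure(list(k = k, mapping = mapping), class = "fold_assignment")
}

#' Specimen-level cross-validation of the cascade
#'
#' For every fold: the intensity normalizer is fitted on the training
#' volumes only, the cascade is trained on the training folds, and all eight
#' metrics are computed on the held-out volumes. Per-volume rows are pooled
#' over folds and summarised as mean and standard deviation.
#'
#' @param data list of `phantom_sample`s (or `list(image =, label =)` pairs).
#' @param cfg a [cascade_config()].
#' @param tcfg a [train_config()].
#' @param k number of folds.
#' @param seed master seed (folds, per-fold training).
#' @param out_dir optional directory: writes `metrics.csv`, `summary.csv`
#'   and `run_manifest.yaml`.
#' @return List with `per_volume` (data.frame), `summary` (data.frame) and
#'   `manifest` (list; includes per-fold normalizer statistics).
#' @export
run_crossval <- function(data, cfg, tcfg, k = 4L, seed = 1L, out_dir = NULL) {
  n <- length(data)
  if (n < k) stop("run_crossval: fewer samples than folds")
  ids <- paste0("vol", seq_len(n))
  folds <- make_folds(ids, k, seed)
  fold_seeds <- derive_seeds(seed + 1L, k)
  rows <- list()
  fold_norms <- list()
  for (f in seq_len(k)) {
    test_idx <- which(folds$mapping == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    tc <- tcfg; tc$seed <- fold_seeds[f]
    cm <- train_cascade(data[train_idx], cfg, tc)
    fold_norms[[f]] <- list(mean = cm$normalizer$mean, std = cm$normalizer$std)
    for (i in test_idx) {
      pred <- run_cascade(cm, data[[i]]$image)
      row <- evaluate_pair(pred, data[[i]]$label,
                           spacing = data[[i]]$image$spacing)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(volume = ids[i], fold = f), row)
    }
  }
  per_volume <- do.call(rbind, rows)
  summary <- summarise_metrics(per_volume[-(1:2)])
  manifest <- list(k = k, seed = seed, n_volumes = n,
                   fold_mapping = as.list(folds$mapping),
                   fold_normalizers = fold_norms,
                   train_config = unclass(tcfg),
                   threshold = cfg$threshold,
                   connectivity = cfg$connectivity,
                   axis_order = cfg$axis_order,
                   data_hashes = vapply(data, function(d)
                     digest_volume(d$image), ""))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_volume, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  }
  list(per_volume = per_volume, summary = summary, manifest = manifest)
}

# cheap content hash for run manifests (sum-based; not cryptographic)
digest_volume <- function(v) {
  x <- as.vector(v$data)
  sprintf("%.10e:%.10e:%d", sum(x), sum(x * seq_along(x) %% 97), length(x))
}

#' Compare a single-orientation baseline against the auto-context cascade
#'
#' Trains (a) one 2D network of the given architecture on a single slice
#' orientation followed by largest-component post-processing, and (b) the
#' three-stage cascade of the same architecture, on the same training split
#' and with the same per-network training budget. Both are evaluated on the
#' held-out volumes; per-metric paired Wilcoxon p-values are reported when
#' enough non-degenerate pairs exist.
#'
#' @param data list of samples.
#' @param arch `"unet"`, `"resunet"` or `"seunet"`.
#' @param train_idx,test_idx index vectors splitting `data`.
#' @param stage_template a [seg_model_config()] whose depth/filters/input
#'   size are used for all networks (its `arch` and `in_channels` are
#'   overridden).
#' @param tcfg a [train_config()].
#' @param baseline_axis slicing orientation of the baseline network.
#' @param axis_order cascade stage orientations.
#' @param threshold,connectivity post-processing parameters.
#' @param seed seed for both trainings.
#' @return List with `per_volume` (rows for both systems), `comparison`
#'   (mean/sd per metric per system plus p-values), and the two fitted
#'   models.
#' @export
compare_frameworks <- function(data, arch, train_idx, test_idx,
                               stage_template = seg_model_config("unet"),
                               tcfg = train_config(),
                               baseline_axis = "axial",
                               axis_order = c("coronal", "sagittal", "axial"),
                               threshold = 0.5, connectivity = 26L,
                               seed = 1L) {
  stage_cfgs <- lapply(1:3, function(s) {
    cfg <- stage_template; cfg$arch <- arch; cfg$in_channels <- s
    do.call(seg_model_config, unclass(cfg))
  })
  ccfg <- cascade_config(axis_order, threshold, connectivity, stage_cfgs)
  tc <- tcfg; tc$seed <- seed
  cas <- train_cascade(data[train_idx], ccfg, tc)

  # baseline: one network on one orientation + largest-component refinement
  images <- lapply(data[train_idx], `[[`, "image")
  norm <- fit_normalizer(images)
  bx <- lapply(data[train_idx], function(d)
    extract_slices(apply_normalizer(norm, d$image), baseline_axis)$slices)
  by <- lapply(data[train_idx], function(d)
    extract_slices(d$label, baseline_axis)$slices)
  bmodel <- build_model(stage_cfgs[[1]], seed = seed)
  bt <- tcfg; bt$seed <- seed
  bmodel <- train_stage_model(bmodel, bind_slices(bx), bind_slices(by), bt)

  predict_baseline <- function(img) {
    nimg <- apply_normalizer(norm, img)
    stk <- extract_slices(nimg, baseline_axis)
    pvol <- assemble_volume(predict_stack(bmodel, stk), img)
    suppressWarnings(largest_component(binarize(pvol, threshold), connectivity))
  }

  rows <- list()
  for (i in test_idx) {
    gt <- data[[i]]$label
    sp <- data[[i]]$image$spacing
    pb <- predict_baseline(data[[i]]$image)
    pc <- run_cascade(cas, data[[i]]$image)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(volume = paste0("vol", i), system = "baseline"),
      evaluate_pair(pb, gt, spacing = sp))
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(volume = paste0("vol", i), system = "autocascade"),
      evaluate_pair(pc, gt, spacing = sp))
  }
  per_volume <- do.call(rbind, rows)
  metrics <- c("dice", "jaccard", "accuracy", "precision", "recall",
               "specificity", "auc", "hausdorff_mm")
  comp <- do.call(rbind, lapply(metrics, function(mname) {
    a <- per_volume[per_volume$system == "autocascade", mname]
    b <- per_volume[per_volume$system == "baseline", mname]
    p <- tryCatch(wilcoxon_paired(a[!is.na(a) & !is.na(b)],
                                  b[!is.na(a) & !is.na(b)]),
                  error = function(e) NA_real_)
    data.frame(metric = mname,
               baseline_mean = mean(b, na.rm = TRUE),
               baseline_sd = stats::sd(b, na.rm = TRUE),
               autocascade_mean = mean(a, na.rm = TRUE),
               autocascade_sd = stats::sd(a, na.rm = TRUE),
               p_value = p)
  }))
  list(per_volume = per_volume, comparison = comp,
       cascade = cas, baseline = bmodel)
}
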